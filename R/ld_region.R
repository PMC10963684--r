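#' Pairwise LD (r squared) between two genotype vectors
#'
#' Squared Pearson correlation of allele codes over pairwise-complete
#' accessions. Multiallelic codes are first collapsed to reference vs any
#' alternate (0/1). If either vector is monomorphic over the complete pairs,
#' r^2 is undefined and `NA` is returned (not 0).
#'
#' @param gA,gB Integer genotype vectors of equal length (0 = ref, >=1 = alt,
#'   NA = missing).
#' @return r^2 in `[0, 1]`, or `NA` if undefined.
#' @export
r_squared <- function(gA, gB) {
  if (length(gA) != length(gB)) stop("r_squared: genotype vectors differ in length")
  a <- as.integer(gA > 0); b <- as.integer(gB > 0)
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) stop("r_squared: fewer than 2 pairwise-complete observations")
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Pairwise LD matrix over a variant set
#'
#' @param vs A [variant_set()] (sites assumed sorted by position).
#' @return An object of class `ld_matrix`: list with `positions` and the
#'   symmetric `r2` matrix (`NA` where undefined; diagonal 1 for polymorphic
#'   sites).
#' @export
ld_matrix <- function(vs) {
  g <- vs$geno > 0
  mode(g) <- "integer"
  n <- nrow(g)
  r2 <- matrix(NA_real_, n, n)
  poly <- apply(g, 1L, function(x) {
    x <- x[!is.na(x)]
    length(x) >= 2L && stats::var(x) > 0
  })
  for (i in seq_len(n)) {
    if (!poly[i]) next
    r2[i, i] <- 1
    for (j in seq_len(i - 1L)) {
      if (!poly[j]) next
      r2[i, j] <- r2[j, i] <- tryCatch(r_squared(g[i, ], g[j, ]),
                                       error = function(e) NA_real_)
    }
  }
  structure(list(positions = vs$sites$pos, chrom = vs$sites$chrom[1], r2 = r2),
            class = "ld_matrix")
}

#' Delimit the LD block around an association peak
#'
#' Finds the maximal contiguous run of sites containing the peak in which
#' every site has r^2 >= `r2_min` with the peak site, and returns the genomic
#' interval spanned by those sites (1-based inclusive). This is the simple,
#' reproducible analogue of reading the high-LD triangle off an LD heat map.
#'
#' @param ld An [ld_matrix()].
#' @param peak Genomic position of the peak site (must be one of
#'   `ld$positions`).
#' @param r2_min LD threshold (default 0.6).
#' @return Integer vector `c(start, end)`.
#' @export
ld_block <- function(ld, peak, r2_min = 0.6) {
  p <- match(peak, ld$positions)
  if (is.na(p)) stop("ld_block: peak position not among LD matrix sites")
  if (is.na(ld$r2[p, p])) stop("ld_block: peak site is monomorphic, LD undefined")
  with_peak <- ld$r2[, p]
  ok <- !is.na(with_peak) & with_peak >= r2_min
  ok[p] <- TRUE
  lo <- p
  while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- p
  while (hi < length(ok) && ok[hi + 1L]) hi <- hi + 1L
  c(ld$positions[lo], ld$positions[hi])
}

#' Summarize a candidate interval: span and overlapping genes
#'
#' A gene is included iff its `[start, end]` span overlaps the interval by at
#' least 1 bp.
#'
#' @param interval Integer vector `c(start, end)`, 1-based inclusive.
#' @param genes List of [gene_model()] objects.
#' @param chrom Optional chromosome name; when given, only genes on that
#'   chromosome are considered.
#' @return List with `span_kb`, `interval` and `genes` (the overlapping
#'   gene models) plus `gene_ids`.
#' @export
region_report <- function(interval, genes, chrom = NULL) {
  stopifnot(length(interval) == 2L, interval[1] <= interval[2])
  hit <- vapply(genes, function(g) {
    (is.null(chrom) || g$chrom == chrom) &&
      g$start <= interval[2] && g$end >= interval[1]
  }, logical(1))
  sel <- genes[hit]
  list(span_kb = (interval[2] - interval[1] + 1) / 1000,
       interval = interval,
       genes = sel,
       gene_ids = vapply(sel, function(g) g$gene_id, character(1)))
}
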