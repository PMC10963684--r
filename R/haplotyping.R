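#' Collect the variant sites that define a gene's haplotypes
#'
#' Default region set is promoter + CDS: a site is retained when its position
#' falls inside [promoter_interval()] of the gene or inside any CDS interval.
#' `regions = "gene"` switches to whole-gene mode (any site within the gene
#' span or its promoter is kept only if listed). Sites are returned ordered
#' by position.
#'
#' @param vs A [variant_set()].
#' @param gene A [gene_model()].
#' @param regions Character subset of `c("promoter", "cds", "gene")`.
#' @param promoter_len Promoter length in bp (default 1000).
#' @return A [variant_set()] restricted to the selected sites.
#' @export
collect_gene_variants <- function(vs, gene, regions = c("promoter", "cds"),
                                  promoter_len = 1000) {
  regions <- match.arg(tolower(regions), c("promoter", "cds", "gene"),
                       several.ok = TRUE)
  pos <- vs$sites$pos
  on_chrom <- vs$sites$chrom == gene$chrom
  keep <- rep(FALSE, length(pos))
  if ("promoter" %in% regions) {
    pr <- promoter_interval(gene, promoter_len)
    keep <- keep | (pos >= pr[1] & pos <= pr[2])
  }
  if ("cds" %in% regions && nrow(gene$cds)) {
    for (i in seq_len(nrow(gene$cds)))
      keep <- keep | (pos >= gene$cds$start[i] & pos <= gene$cds$end[i])
  }
  if ("gene" %in% regions)
    keep <- keep | (pos >= gene$start & pos <= gene$end)
  idx <- which(keep & on_chrom)
  vs_subset(vs, idx[order(pos[idx])])
}

#' Enumerate gene haplotypes from a set of variant sites
#'
#' Each accession with complete (non-missing) allele codes at all sites gets
#' the signature of its allele tuple; accessions missing any code are left
#' unassigned. Distinct signatures become haplotypes labelled `Hap1`,
#' `Hap2`, ... in descending order of accession count (ties broken by first
#' occurrence in accession order).
#'
#' @param vs A [variant_set()] of the sites to use (>= 1 site).
#' @param gene_id Identifier carried through to the result.
#' @return An object of class `gene_haplotypes`: list with `gene_id`,
#'   `sites` (the site table), `signatures` (haplotype x site integer
#'   matrix), `counts` (named, descending), `assignments` (named character
#'   vector accession -> haplotype id, `NA` when unassigned) and
#'   `n_accessions`.
#' @export
enumerate_haplotypes <- function(vs, gene_id = NA_character_) {
  if (nrow(vs$sites) == 0L) stop("enumerate_haplotypes: zero variant sites")
  g <- vs$geno
  complete <- colSums(is.na(g)) == 0L
  sig <- apply(g, 2L, paste, collapse = ":")
  sig[!complete] <- NA_character_
  tab <- table(factor(sig, levels = unique(sig[!is.na(sig)])))
  # descending count, ties by first occurrence (factor levels preserve order)
  ord <- order(-as.integer(tab), seq_along(tab))
  keys <- names(tab)[ord]
  ids <- paste0("Hap", seq_along(keys))
  assignments <- stats::setNames(ids[match(sig, keys)], colnames(g))
  signatures <- if (length(keys)) {
    do.call(rbind, lapply(strsplit(keys, ":", fixed = TRUE), as.integer))
  } else matrix(integer(0), 0, nrow(g))
  rownames(signatures) <- ids
  structure(list(gene_id = gene_id, sites = vs$sites,
                 signatures = signatures,
                 counts = stats::setNames(as.integer(tab)[ord], ids),
                 assignments = assignments,
                 n_accessions = ncol(g)),
            class = "gene_haplotypes")
}

#' @export
print.gene_haplotypes <- function(x, ...) {
  cat(sprintf("gene_haplotypes %s: %d site(s), %d haplotype(s), %d/%d accessions assigned\n",
              x$gene_id, nrow(x$sites), length(x$counts),
              sum(!is.na(x$assignments)), x$n_accessions))
  print(x$counts)
  invisible(x)
}

#' Restrict to major haplotypes
#'
#' Keeps haplotypes carried by at least `min_count` accessions ("more than 10
#' accessions" read strictly, hence the default 11). Accessions of dropped
#' haplotypes become unassigned; retained haplotypes keep their ids.
#'
#' @param gh A `gene_haplotypes` object.
#' @param min_count Minimum accession count (default 11).
#' @return A filtered `gene_haplotypes`.
#' @export
major_haplotypes <- function(gh, min_count = 11) {
  keep <- names(gh$counts)[gh$counts >= min_count]
  asg <- gh$assignments
  asg[!asg %in% keep] <- NA_character_
  gh$counts <- gh$counts[keep]
  gh$signatures <- gh$signatures[keep, , drop = FALSE]
  gh$assignments <- asg
  gh
}

#' Identify the haplotype matching the reference genome
#'
#' The reference carries allele code 0 at every site; returns that
#' haplotype's id, or `NA` if no accession carries the all-reference
#' signature.
#'
#' @param gh A `gene_haplotypes` object.
#' @return Haplotype id or `NA`.
#' @export
reference_haplotype <- function(gh) {
  hit <- which(rowSums(gh$signatures != 0L) == 0L)
  if (length(hit)) rownames(gh$signatures)[hit[1]] else NA_character_
}

#' Write a per-gene haplotype report as TSV
#'
#' One row per haplotype: gene_id, hap_id, count, colon-joined signature and
#' comma-joined accession list.
#'
#' @param gh A `gene_haplotypes` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_report <- function(gh, path) {
  ids <- names(gh$counts)
  tab <- data.table::data.table(
    gene_id = gh$gene_id,
    hap_id = ids,
    count = as.integer(gh$counts),
    signature = vapply(ids, function(h)
      paste(gh$signatures[h, ], collapse = ":"), character(1)),
    accessions = vapply(ids, function(h)
      paste(names(gh$assignments)[!is.na(gh$assignments) & gh$assignments == h],
            collapse = ","), character(1)))
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}
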