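#' Classify a variant site as SNP, INDEL or PAV
#'
#' A site is a `SNP` when every allele (reference and all alternates) has
#' length 1; it is a `PAV` (presence/absence variant) when the largest
#' absolute length difference between the reference and any alternate
#' exceeds 50 bp; everything else is an `INDEL`. Symbolic structural alleles
#' (e.g. `<DEL>`) are classified through `svlen` when supplied: `PAV` if
#' `|svlen| > 50`, otherwise `INDEL`.
#'
#' @param ref Reference allele string.
#' @param alts Character vector of alternate allele strings.
#' @param svlen Optional numeric SVLEN for symbolic alternates.
#' @return One of `"SNP"`, `"INDEL"`, `"PAV"`.
#' @examples
#' classify_variant("A", "G")   # SNP
#' classify_variant("AT", "A")  # INDEL
#' classify_variant(strrep("A", 421), "A")  # PAV
#' @export
classify_variant <- function(ref, alts, svlen = NULL) {
  stopifnot(is.character(ref), length(ref) == 1L, is.character(alts))
  if (!nzchar(ref) || any(!nzchar(alts)) || length(alts) == 0L)
    stop("classify_variant: empty allele string")
  symbolic <- grepl("^<", alts)
  if (any(symbolic)) {
    len <- if (!is.null(svlen)) suppressWarnings(max(abs(as.numeric(svlen)), na.rm = TRUE)) else NA_real_
    if (is.finite(len) && len > 50) return("PAV")
    # a symbolic ALT without usable SVLEN is still a length-changing event
    return("INDEL")
  }
  if (nchar(ref) == 1L && all(nchar(alts) == 1L)) return("SNP")
  if (max(abs(nchar(alts) - nchar(ref))) > 50) return("PAV")
  "INDEL"
}

#' Variant set container
#'
#' Column-oriented container for a set of variant records: one row of `sites`
#' per retained site (chrom, 1-based pos, ref, comma-joined alts,
#' variant_class) and an integer genotype matrix (`sites x accessions`) with
#' code 0 for the reference allele, `k >= 1` for the k-th alternate, and `NA`
#' for missing (which includes heterozygous diploid calls: the panel is
#' assumed inbred).
#'
#' @param sites data.frame with columns chrom, pos, id, ref, alt,
#'   variant_class.
#' @param geno Integer matrix, one row per site, one column per accession
#'   (column names are accession ids).
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(sites, geno) {
  sites <- data.table::as.data.table(sites)
  stopifnot(all(c("chrom", "pos", "ref", "alt", "variant_class") %in% names(sites)),
            nrow(sites) == nrow(geno))
  if (is.null(sites$id)) sites$id <- rep(NA_character_, nrow(sites))
  if (any(sites$pos < 1)) stop("variant_set: pos must be >= 1")
  n_alt <- lengths(strsplit(sites$alt, ",", fixed = TRUE))
  if (nrow(sites)) {
    mx <- suppressWarnings(apply(geno, 1L, max, na.rm = TRUE))
    mx[!is.finite(mx)] <- 0
    mn <- suppressWarnings(apply(geno, 1L, min, na.rm = TRUE))
    mn[!is.finite(mn)] <- 0
    if (any(mx > n_alt) || any(mn < 0))
      stop("variant_set: genotype code indexes an undefined allele")
  }
  structure(list(sites = sites, geno = geno, samples = colnames(geno)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d sites x %d accessions\n", nrow(x$sites), ncol(x$geno)))
  print(utils::head(x$sites, 6L))
  invisible(x)
}

#' Subset a variant set by site index
#' @param vs A `variant_set`.
#' @param idx Integer or logical index over sites.
#' @return A `variant_set` with the selected sites.
#' @export
vs_subset <- function(vs, idx) {
  variant_set(vs$sites[idx, , drop = FALSE], vs$geno[idx, , drop = FALSE])
}

parse_region <- function(region) {
  if (is.null(region)) return(NULL)
  if (is.character(region) && length(region) == 1L) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L) stop("region must look like 'chr1:100-200'")
    return(list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4])))
  }
  stopifnot(length(region) == 3L)
  list(chrom = as.character(region[[1]]), start = as.integer(region[[2]]),
       end = as.integer(region[[3]]))
}

# quick structural validation so parse errors can name the offending line
validate_vcf_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "##fileformat"))
    stop("malformed VCF: missing ##fileformat header (line 1)")
  hdr <- grep("^#CHROM\t", lines)
  if (!length(hdr)) stop("malformed VCF: missing #CHROM header line")
  nfield <- length(strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]])
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf != nfield)
      stop(sprintf("malformed VCF: line %d has %d fields, expected %d", i, nf, nfield))
  }
  invisible(TRUE)
}

gt_to_code <- function(gt) {
  # "0/0" -> 0, "1|1" -> 1, "0/1" -> NA (het; inbred panel), "./." / "." -> NA,
  # haploid "1" -> 1. Returns list(code, het) where het counts masked calls.
  al <- strsplit(gt, "[/|]")
  ploidy <- lengths(al)
  if (any(ploidy > 2L)) stop("unknown sample ploidy: more than 2 alleles in GT")
  code <- vapply(al, function(a) {
    if (any(a == "." | a == "")) return(NA_integer_)
    u <- unique(a)
    if (length(u) > 1L) return(NA_integer_)  # heterozygous -> missing
    as.integer(u)
  }, integer(1))
  het <- vapply(al, function(a) {
    if (any(a == "." | a == "")) return(FALSE)
    length(unique(a)) > 1L
  }, logical(1))
  list(code = code, het = het)
}

#' Read a VCF into a variant set
#'
#' Reads a VCF 4.x file (plain or gzipped) with one sample column per
#' accession. Homozygous diploid calls are collapsed to a single allele code
#' (`0/0 -> 0`, `1/1 -> 1`); heterozygous calls are set to missing with a
#' logged count, because the panel is assumed inbred and each accession is
#' treated as carrying a single haplotype. Sites are classified with
#' [classify_variant()] (SVLEN is honoured for symbolic alternates).
#'
#' @param path Path to the VCF file.
#' @param region Optional region filter, either `"chr:start-end"` or a
#'   list/vector `(chrom, start, end)`; inclusive on `pos`.
#' @return A [variant_set()]; attribute `n_het_masked` holds the number of
#'   heterozygous calls converted to missing.
#' @export
read_vcf <- function(path, region = NULL) {
  validate_vcf_lines(path)
  vcf <- tryCatch(VariantAnnotation::readVcf(path),
                  error = function(e) stop("VCF parse error in ", path, ": ",
                                           conditionMessage(e)))
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alt0 <- VariantAnnotation::alt(vcf)
  alts <- lapply(seq_along(alt0), function(i) as.character(alt0[[i]]))
  ids <- names(rr)
  svlen <- tryCatch(VariantAnnotation::info(vcf)$SVLEN, error = function(e) NULL)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT genotypes")
  keep <- seq_along(pos)
  reg <- parse_region(region)
  if (!is.null(reg))
    keep <- which(chrom == reg$chrom & pos >= reg$start & pos <= reg$end)
  n_het <- 0L
  geno <- matrix(NA_integer_, length(keep), ncol(gt),
                 dimnames = list(NULL, colnames(gt)))
  for (j in seq_along(keep)) {
    parsed <- gt_to_code(gt[keep[j], ])
    geno[j, ] <- parsed$code
    n_het <- n_het + sum(parsed$het)
  }
  if (n_het > 0)
    message(sprintf("read_vcf: masked %d heterozygous call(s) as missing (inbred panel)", n_het))
  cls <- vapply(keep, function(i) {
    sv <- if (!is.null(svlen)) unlist(svlen[i]) else NULL
    classify_variant(refs[i], alts[[i]], svlen = sv)
  }, character(1))
  sites <- data.table::data.table(
    chrom = chrom[keep], pos = pos[keep],
    id = if (is.null(ids)) NA_character_ else ids[keep],
    ref = refs[keep],
    alt = vapply(alts[keep], paste, character(1), collapse = ","),
    variant_class = cls)
  out <- variant_set(sites, geno)
  attr(out, "n_het_masked") <- n_het
  out
}

#' Write a variant set to a VCF file
#'
#' Emits a minimal VCF 4.2 with a GT FORMAT field; allele codes are written
#' as homozygous diploid genotypes (`0 -> 0/0`), missing as `./.`. A path
#' ending in `.gz` is bgzip-compressed (htslib-seekable).
#'
#' @param vs A [variant_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path) {
  if (grepl("\\.gz$", path)) {
    tmp <- tempfile(fileext = ".vcf")
    on.exit(unlink(tmp), add = TRUE)
    write_vcf(vs, tmp)
    Rsamtools::bgzip(tmp, dest = path, overwrite = TRUE)
    return(invisible(path))
  }
  s <- vs$sites
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=haplomine",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vs$samples), collapse = "\t"))
  gtxt <- apply(vs$geno, 1L, function(g)
    ifelse(is.na(g), "./.", paste0(g, "/", g)))
  if (is.null(dim(gtxt))) gtxt <- matrix(gtxt, nrow = 1L)
  else gtxt <- t(gtxt)
  body <- vapply(seq_len(nrow(s)), function(i) {
    paste(c(s$chrom[i], s$pos[i],
            if (is.na(s$id[i])) "." else s$id[i],
            s$ref[i], s$alt[i], ".", "PASS", ".", "GT", gtxt[i, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' Gene model
#'
#' A gene with 1-based inclusive coordinates, strand, CDS intervals and a
#' transcription start site. On the + strand the TSS defaults to `start`, on
#' the - strand to `end`, unless an mRNA feature supplies a transcript
#' boundary.
#'
#' @param gene_id Identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based inclusive gene span.
#' @param cds data.frame with columns `start`, `end` (1-based inclusive), or
#'   NULL for none.
#' @param tss Optional TSS; derived from strand and span when NULL.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, start, end, cds = NULL, tss = NULL) {
  if (!strand %in% c("+", "-")) stop("gene ", gene_id, " has no usable strand")
  start <- as.integer(start); end <- as.integer(end)
  if (start > end) stop("gene ", gene_id, ": start > end")
  if (is.null(cds)) cds <- data.frame(start = integer(0), end = integer(0))
  cds <- as.data.frame(cds)[, c("start", "end")]
  if (nrow(cds) && (any(cds$start < start) || any(cds$end > end)))
    stop("gene ", gene_id, ": CDS interval outside gene span")
  cds <- cds[order(cds$start), , drop = FALSE]
  if (is.null(tss)) tss <- if (strand == "+") start else end
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 start = start, end = end, cds = cds, tss = as.integer(tss)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s %s:%d-%d (%s), tss=%d, %d CDS interval(s)\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand, x$tss, nrow(x$cds)))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Collects one [gene_model()] per `gene` feature; CDS intervals are gathered
#' from descendant features (CDS children of the gene or of its mRNAs). When
#' an mRNA is present its 5' boundary supplies the TSS; otherwise the gene
#' boundary is used. Genes are returned sorted by (chrom, start).
#'
#' @param path Path to a GFF3 file (plain or gzipped).
#' @return A list of `gene_model` objects.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- gr$ID
  parents <- gr$Parent
  parent1 <- vapply(seq_along(gr), function(i) {
    p <- parents[[i]]
    if (length(p)) as.character(p[1]) else NA_character_
  }, character(1))
  gi <- which(type == "gene")
  if (!length(gi)) return(list())
  # map every feature to its owning gene id (1 level of mRNA indirection)
  id2gene <- stats::setNames(ids[gi], ids[gi])
  mi <- which(type %in% c("mRNA", "transcript"))
  for (i in mi) if (!is.na(parent1[i]) && parent1[i] %in% names(id2gene))
    id2gene[[ids[i]]] <- id2gene[[parent1[i]]]
  genes <- lapply(gi, function(i) {
    gid <- ids[i]
    strand <- as.character(GenomicRanges::strand(gr)[i])
    if (!strand %in% c("+", "-")) stop("gene ", gid, " has no usable strand")
    owners <- names(id2gene)[id2gene == gid]
    ci <- which(type == "CDS" & parent1 %in% owners)
    cds <- if (length(ci))
      data.frame(start = GenomicRanges::start(gr)[ci], end = GenomicRanges::end(gr)[ci])
    else NULL
    # transcript 5' boundary defines the TSS when annotated
    tss <- NULL
    ti <- which(type %in% c("mRNA", "transcript") & parent1 == gid)
    if (length(ti)) {
      tss <- if (strand == "+") min(GenomicRanges::start(gr)[ti])
             else max(GenomicRanges::end(gr)[ti])
    }
    gene_model(gid, as.character(GenomicRanges::seqnames(gr)[i]), strand,
               GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i],
               cds = cds, tss = tss)
  })
  ord <- order(vapply(genes, function(g) g$chrom, character(1)),
               vapply(genes, function(g) g$start, integer(1)))
  genes[ord]
}

#' Write gene models to a GFF3 file
#' @param genes List of [gene_model()] objects.
#' @param path Output path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  lines <- "##gff-version 3"
  for (g in genes) {
    lines <- c(lines, paste(g$chrom, "haplomine", "gene", g$start, g$end, ".",
                            g$strand, ".", paste0("ID=", g$gene_id), sep = "\t"))
    mid <- paste0(g$gene_id, ".1")
    m_start <- if (g$strand == "+") g$tss else g$start
    m_end <- if (g$strand == "+") g$end else g$tss
    lines <- c(lines, paste(g$chrom, "haplomine", "mRNA", m_start, m_end, ".",
                            g$strand, ".", paste0("ID=", mid, ";Parent=", g$gene_id),
                            sep = "\t"))
    if (nrow(g$cds))
      for (i in seq_len(nrow(g$cds)))
        lines <- c(lines, paste(g$chrom, "haplomine", "CDS", g$cds$start[i],
                                g$cds$end[i], ".", g$strand, "0",
                                paste0("ID=", mid, ".cds;Parent=", mid), sep = "\t"))
  }
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Promoter interval for a gene
#'
#' The promoter is the `length` bp immediately upstream of the TSS: on the +
#' strand `[tss - length, tss - 1]`, on the - strand `[tss + 1, tss + length]`.
#' The lower bound is clipped at 1, so near a chromosome start the interval
#' may be shorter than `length`.
#'
#' @param gene A [gene_model()].
#' @param length Promoter length in bp (default 1000, i.e. 1 kb upstream of
#'   the transcription initiation site).
#' @return Integer vector `c(start, end)`, 1-based inclusive.
#' @export
promoter_interval <- function(gene, length = 1000) {
  stopifnot(length >= 1)
  if (gene$strand == "+") {
    c(max(1L, gene$tss - as.integer(length)), gene$tss - 1L)
  } else {
    c(gene$tss + 1L, gene$tss + as.integer(length))
  }
}

#' Read a long-format phenotype table
#'
#' Expects a delimited file with header columns `accession`, `trait`,
#' `environment`, `value` (cm). Rows with non-finite or non-numeric values
#' are dropped with a warning naming the count; replicate rows for the same
#' (accession, trait, environment) key are averaged.
#'
#' @param path Path to a CSV/TSV file (plain or gzipped; delimiter sniffed).
# fread with in-R gzip support (fread's own .gz path needs R.utils)
fread_any <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    txt <- paste(readLines(con, warn = FALSE), collapse = "\n")
    if (!nzchar(txt)) return(data.table::data.table())
    data.table::fread(text = txt, ...)
  } else data.table::fread(path, ...)
}

#' @return A `data.table` with one row per (accession, trait, environment).
#' @export
read_phenotypes <- function(path) {
  ph <- fread_any(path, colClasses = list(character = 1))
  need <- c("accession", "trait", "environment", "value")
  miss <- setdiff(need, names(ph))
  if (length(miss)) stop("phenotype file missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(ph)) return(ph[, need, with = FALSE])
  ph$value <- suppressWarnings(as.numeric(ph$value))
  bad <- !is.finite(ph$value)
  if (any(bad)) {
    warning(sprintf("read_phenotypes: dropped %d row(s) with missing/non-numeric values", sum(bad)))
    ph <- ph[!bad]
  }
  value <- NULL # appease R CMD check / data.table NSE
  ph[, list(value = mean(value)), by = c("accession", "trait", "environment")]
}

#' Write a phenotype table to CSV
#' @param phen data.frame/data.table with columns accession, trait,
#'   environment, value.
#' @param path Output path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phen, path) {
  data.table::fwrite(data.table::as.data.table(phen), path)
  invisible(path)
}

#' Read a group-summary table (label, n, mean, sd)
#'
#' Summary-statistics mode input: one row per group with its sample size,
#' mean and standard deviation (cm), as printed in publication tables.
#'
#' @param path Path to a delimited file with header label,n,mean,sd.
#' @return A `data.table` with those four columns.
#' @export
read_group_summaries <- function(path) {
  gs <- fread_any(path)
  need <- c("label", "n", "mean", "sd")
  miss <- setdiff(need, names(gs))
  if (length(miss)) stop("summary file missing column(s): ", paste(miss, collapse = ", "))
  gs <- gs[, need, with = FALSE]
  if (any(gs$n < 1)) stop("group summary: n must be >= 1")
  if (any(gs$sd < 0, na.rm = TRUE)) stop("group summary: sd must be >= 0")
  if (any(gs$n < 2 & gs$sd > 0)) stop("group summary: sd requires n >= 2")
  gs
}
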