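# The generator states a fixed "world": a rice-like inbred diversity panel
# of 343 accessions, one causal gene whose 4 haplotypes are built from ~20
# promoter variants (one InDel) plus CDS SNPs and a ~400 bp PAV, surrounded
# by null genes with haplotype structure but no effect; shoot length (SL) in
# three seedling environments and plant height (PH) at two locations share
# the causal haplotype effect (scaled per trait), inducing a positive SL-PH
# genetic correlation. Effect magnitudes and haplotype frequencies default
# to published-table scale (group means ~92/121/137/137 cm at n
# 25/91/28/46, residual SD ~20 cm for PH).

default_traits <- function() {
  list(
    SL = list(baseline = 27.7, effect_scale = 0.27, residual_sd = 3.5,
              environments = c(GST = 0, GSF = -3.3, DST = -8.9)),
    PH = list(baseline = 91.5, effect_scale = 1, residual_sd = 20,
              environments = c(Guangzhou = 0, Yangjiang = 2)))
}

default_gene_cfg <- function(gene_id, start, causal = FALSE, n_haps = 3) {
  if (causal) {
    list(gene_id = gene_id, start = start, end = start + 4999L,
         n_promoter = 20L, n_cds = 3L, include_pav = TRUE,
         hap_freq = c(25, 91, 28, 46) / 190,
         effects = c(0, 29, 45, 45.5))
  } else {
    freq <- switch(as.character(n_haps),
                   "2" = c(0.55, 0.45),
                   "3" = c(0.4, 0.35, 0.25),
                   c(0.3, 0.3, 0.2, 0.2))
    list(gene_id = gene_id, start = start, end = start + 4999L,
         n_promoter = 3L, n_cds = 1L, include_pav = FALSE,
         hap_freq = freq, effects = rep(0, length(freq)))
  }
}

#' Simulation configuration for a synthetic genotype-phenotype panel
#'
#' Defaults describe the emulated study panel: 343 inbred accessions; a
#' region of `1 + n_null_genes` genes on one chromosome, gene 5 causal with
#' four haplotypes at frequencies (25, 91, 28, 46)/190 and additive effects
#' (0, 29, 45, 45.5) cm on the plant-height scale; SL measured under GST,
#' GSF, DST and PH at two locations, sharing the haplotype effect with
#' per-trait scaling.
#'
#' @param n_accessions Panel size (default 343).
#' @param n_null_genes Number of effect-free genes around the causal gene
#'   (default 9, giving a 10-gene region).
#' @param causal_index Which gene (1-based along the region) is causal
#'   (default 5).
#' @param genes Optional explicit list of gene configurations (overrides the
#'   defaults); each is a list with gene_id, start, end, n_promoter, n_cds,
#'   include_pav, hap_freq, effects.
#' @param traits Optional trait list (see `default_traits` in the source).
#' @param chrom Chromosome name.
#' @param seed Master seed; all random streams derive from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_accessions = 343, n_null_genes = 9, causal_index = 5,
                       genes = NULL, traits = NULL, chrom = "chr1", seed = 1) {
  if (is.null(genes)) {
    n_genes <- n_null_genes + 1L
    stopifnot(causal_index >= 1, causal_index <= n_genes)
    starts <- 38000000L + (seq_len(n_genes) - 1L) * 20000L
    genes <- lapply(seq_len(n_genes), function(i)
      default_gene_cfg(sprintf("gene%02d", i), starts[i],
                       causal = (i == causal_index),
                       n_haps = 2 + (i %% 3)))
  }
  for (g in genes) {
    if (abs(sum(g$hap_freq) - 1) > 1e-8) stop("hap_freq must sum to 1 for ", g$gene_id)
    if (any(g$hap_freq <= 0)) stop("degenerate hap_freq for ", g$gene_id)
    if (length(g$effects) != length(g$hap_freq))
      stop("effects/hap_freq length mismatch for ", g$gene_id)
  }
  traits <- traits %||% default_traits()
  for (tr in traits) if (tr$residual_sd < 0) stop("residual_sd must be >= 0")
  structure(list(n_accessions = as.integer(n_accessions), chrom = chrom,
                 genes = genes, traits = traits, seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic gene model for a configured gene: + strand, single CDS block
sim_gene_model <- function(gcfg, chrom) {
  gene_model(gcfg$gene_id, chrom, "+", gcfg$start, gcfg$end,
             cds = data.frame(start = gcfg$start + 1500L, end = gcfg$start + 4500L))
}

# haplotype x site signature matrix with distinct rows: binary code of the
# haplotype index tiled across sites; the PAV column is carried by hap 1
# only. Haplotype 2 gets the all-zero code, i.e. matches the reference
# genome (mirrors the emulated gene, whose second haplotype is Nipponbare).
sim_signatures <- function(n_haps, n_sites, pav_col = NULL) {
  b <- max(1L, ceiling(log2(n_haps)))
  ord <- seq_len(n_haps) - 1L
  if (n_haps >= 2) ord[1:2] <- c(1L, 0L)
  code <- sapply(ord, function(h) as.integer(intToBits(h))[seq_len(b)])
  code <- matrix(code, nrow = b)  # b x n_haps
  sig <- t(code[((seq_len(n_sites) - 1L) %% b) + 1L, , drop = FALSE])
  if (!is.null(pav_col)) sig[, pav_col] <- as.integer(seq_len(n_haps) == 1L)
  storage.mode(sig) <- "integer"
  sig
}

# site table for one gene: n_promoter sites in the 1 kb promoter (site 1 an
# InDel), n_cds sites in the CDS (last one a ~400 bp PAV when requested)
sim_gene_sites <- function(gcfg, gm) {
  pr <- promoter_interval(gm, 1000)
  p_pos <- as.integer(round(seq(pr[1], pr[2], length.out = gcfg$n_promoter + 2L)))[
    seq_len(gcfg$n_promoter) + 1L]
  c_pos <- as.integer(round(seq(gm$cds$start[1], gm$cds$end[1],
                                length.out = gcfg$n_cds + 2L)))[seq_len(gcfg$n_cds) + 1L]
  pos <- c(p_pos, c_pos)
  ref <- rep("A", length(pos)); alt <- rep("G", length(pos))
  if (gcfg$n_promoter >= 1L) { ref[1] <- "AC"; alt[1] <- "A" }  # promoter InDel
  pav_col <- NULL
  if (isTRUE(gcfg$include_pav) && gcfg$n_cds >= 1L) {
    pav_col <- length(pos)                      # last CDS site
    ref[pav_col] <- strrep("A", 401L)           # ~400 bp deletion
    alt[pav_col] <- "A"
  }
  cls <- vapply(seq_along(pos), function(i) classify_variant(ref[i], alt[i]),
                character(1))
  list(sites = data.table::data.table(chrom = gm$chrom, pos = pos,
                                      id = sprintf("%s_v%02d", gcfg$gene_id,
                                                   seq_along(pos)),
                                      ref = ref, alt = alt, variant_class = cls),
       pav_col = pav_col)
}

# draw haplotype labels and expand to a genotype matrix for one gene
sim_gene_genotypes <- function(gcfg, gm, n_accessions, samples, seed, stream) {
  st <- sim_gene_sites(gcfg, gm)
  labels <- with_stream(seed, stream,
                        sample(seq_along(gcfg$hap_freq), n_accessions,
                               replace = TRUE, prob = gcfg$hap_freq))
  sig <- sim_signatures(length(gcfg$hap_freq), nrow(st$sites), st$pav_col)
  geno <- t(sig[labels, , drop = FALSE])
  colnames(geno) <- samples
  list(sites = st$sites, geno = geno, labels = labels)
}

#' Simulate a genotype-phenotype panel
#'
#' Draws per-accession haplotype labels for every configured gene
#' (multinomial at the configured frequencies), expands them to variant
#' genotypes whose signatures are in bijection with the labels (so
#' within-gene LD is total — the haplotype is the causal unit), and
#' simulates phenotypes as
#' `baseline + environment offset + effect_scale * effect[label] + N(0, residual_sd)`.
#' Genotype assignment and phenotype noise use separate random streams
#' derived from the master seed, so the same genotypes can be re-phenotyped
#' independently.
#'
#' @param cfg A [sim_config()].
#' @return List with `variants` ([variant_set()]), `genes` (list of
#'   [gene_model()]), `phenotypes` (long data.table), `assignments` (named
#'   list gene_id -> integer haplotype labels), `config`.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  samples <- sprintf("acc%03d", seq_len(cfg$n_accessions))
  gms <- lapply(cfg$genes, sim_gene_model, chrom = cfg$chrom)
  sim <- lapply(seq_along(cfg$genes), function(i)
    sim_gene_genotypes(cfg$genes[[i]], gms[[i]], cfg$n_accessions, samples,
                       cfg$seed, paste0("genotypes:", cfg$genes[[i]]$gene_id)))
  sites <- data.table::rbindlist(lapply(sim, `[[`, "sites"))
  geno <- do.call(rbind, lapply(sim, `[[`, "geno"))
  ord <- order(sites$chrom, sites$pos)
  vs <- variant_set(sites[ord], geno[ord, , drop = FALSE])
  assignments <- stats::setNames(lapply(sim, `[[`, "labels"),
                                 vapply(cfg$genes, `[[`, character(1), "gene_id"))
  # genetic value shared across traits: sum of per-gene haplotype effects
  gvalue <- Reduce(`+`, lapply(seq_along(cfg$genes), function(i)
    cfg$genes[[i]]$effects[assignments[[i]]]))
  rows <- list()
  for (tr_name in names(cfg$traits)) {
    tr <- cfg$traits[[tr_name]]
    for (env in names(tr$environments)) {
      noise <- with_stream(cfg$seed, paste0("phenotypes:", tr_name, ":", env),
                           stats::rnorm(cfg$n_accessions, 0, tr$residual_sd))
      rows[[paste(tr_name, env)]] <- data.table::data.table(
        accession = samples, trait = tr_name, environment = env,
        value = tr$baseline + tr$environments[[env]] +
          tr$effect_scale * gvalue + noise)
    }
  }
  list(variants = vs, genes = gms,
       phenotypes = data.table::rbindlist(rows),
       assignments = assignments, config = cfg)
}

#' Generate a null gene: haplotype structure, no phenotype effect
#'
#' Labels are drawn from a fresh random stream keyed by the gene id and seed,
#' independent of every phenotype stream, yielding a gene with realistic
#' haplotype structure but no association.
#'
#' @param n_accessions Panel size (accessions named as in
#'   [simulate_panel()]).
#' @param gene_id Identifier (also keys the random stream).
#' @param start Gene start (1-based); span is 5 kb.
#' @param hap_freq Haplotype frequencies (sum to 1).
#' @param chrom Chromosome name.
#' @param n_promoter,n_cds Variant counts per region.
#' @param seed Master seed.
#' @return List with `variants`, `gene` and `labels`.
#' @export
make_null_gene <- function(n_accessions, gene_id, start, hap_freq = c(0.4, 0.35, 0.25),
                           chrom = "chr1", n_promoter = 3, n_cds = 1, seed = 1) {
  stopifnot(abs(sum(hap_freq) - 1) < 1e-8)
  gcfg <- list(gene_id = gene_id, start = as.integer(start),
               end = as.integer(start) + 4999L, n_promoter = as.integer(n_promoter),
               n_cds = as.integer(n_cds), include_pav = FALSE,
               hap_freq = hap_freq, effects = rep(0, length(hap_freq)))
  gm <- sim_gene_model(gcfg, chrom)
  samples <- sprintf("acc%03d", seq_len(n_accessions))
  g <- sim_gene_genotypes(gcfg, gm, n_accessions, samples, seed,
                          paste0("nullgene:", gene_id))
  list(variants = variant_set(g$sites, g$geno), gene = gm, labels = g$labels)
}

#' Write a simulated panel to standard-format fixture files
#'
#' Emits VCF + GFF3 + long phenotype CSV + a JSON snapshot of the
#' configuration; re-reading with [read_vcf()], [read_gff3()] and
#' [read_phenotypes()] reproduces the in-memory dataset, and re-running
#' [simulate_panel()] on the snapshot reproduces the files byte-for-byte.
#'
#' @param sim Output of [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @param gzip Compress the VCF/GFF3/CSV outputs (default FALSE).
#' @return Named character vector of file paths.
#' @export
write_fixtures <- function(sim, dir, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".gz" else ""
  paths <- c(vcf = file.path(dir, paste0("panel.vcf", ext)),
             gff3 = file.path(dir, paste0("genes.gff3", ext)),
             phenotypes = file.path(dir, paste0("phenotypes.csv", ext)),
             config = file.path(dir, "sim_config.json"))
  write_vcf(sim$variants, paths[["vcf"]])
  write_gff3(sim$genes, paths[["gff3"]])
  write_phenotypes(sim$phenotypes, paths[["phenotypes"]])
  snap <- unclass(sim$config)
  # named vectors serialize as JSON arrays (names lost); store as objects
  snap$traits <- lapply(snap$traits, function(tr) {
    tr$environments <- as.list(tr$environments)
    tr
  })
  jsonlite::write_json(snap, paths[["config"]], auto_unbox = TRUE, digits = NA)
  paths
}

#' Rebuild a simulation configuration from its JSON snapshot
#' @param path Path to `sim_config.json` written by [write_fixtures()].
#' @return A `sim_config`.
#' @export
sim_config_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  genes <- lapply(seq_len(nrow(j$genes) %||% length(j$genes)), function(i) NULL)
  # jsonlite may simplify the gene list to a data.frame; normalize back
  if (is.data.frame(j$genes)) {
    genes <- lapply(seq_len(nrow(j$genes)), function(i) {
      g <- as.list(j$genes[i, ])
      g$hap_freq <- unlist(g$hap_freq); g$effects <- unlist(g$effects)
      g
    })
  } else genes <- j$genes
  traits <- lapply(j$traits, function(tr) {
    tr$environments <- unlist(tr$environments)
    tr
  })
  sim_config(n_accessions = j$n_accessions, genes = genes, traits = traits,
             chrom = j$chrom, seed = j$seed)
}
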