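#' Test one gene's major haplotypes in one environment
#'
#' Groups phenotyped accessions by major haplotype and runs [pooled_anova()]
#' plus [duncan_mrt()]. The gene is significant in this environment when the
#' omnibus p is below `alpha` AND at least one pair of haplotypes shares no
#' compact-display letter; the omnibus guard keeps letter artifacts on tiny
#' groups from counting as signal. Accessions lacking a phenotype in this
#' environment are dropped from this environment only. Fewer than two
#' testable haplotypes gives an untestable (not erroneous) result.
#'
#' @param gh A `gene_haplotypes`, already filtered with [major_haplotypes()].
#' @param phen Phenotype table (accession, trait, environment, value).
#' @param trait,environment Which phenotype column to test.
#' @param alpha Significance level (default 0.05).
#' @return An `environment_result`: list with `gene_id`, `environment`,
#'   `trait`, `n_haplotypes`, `testable`, `significant`, `p`, `duncan`.
#' @export
test_gene <- function(gh, phen, trait, environment, alpha = 0.05) {
  phen <- data.table::as.data.table(phen)
  sel <- which(phen$trait == trait & phen$environment == environment)
  ph <- phen[sel]
  vals <- stats::setNames(ph$value, ph$accession)
  groups <- lapply(names(gh$counts), function(h) {
    acc <- names(gh$assignments)[!is.na(gh$assignments) & gh$assignments == h]
    v <- vals[intersect(acc, names(vals))]
    v[is.finite(v)]
  })
  names(groups) <- names(gh$counts)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  res <- list(gene_id = gh$gene_id, environment = environment, trait = trait,
              n_haplotypes = length(groups), testable = length(groups) >= 2,
              significant = FALSE, p = NA_real_, duncan = NULL)
  if (!res$testable) {
    class(res) <- "environment_result"
    return(res)
  }
  dn <- tryCatch(duncan_mrt(groups, alpha = alpha), error = function(e) NULL)
  if (is.null(dn)) {
    res$testable <- FALSE
    class(res) <- "environment_result"
    return(res)
  }
  res$p <- dn$p
  any_disjoint <- !all(dn$nonsig)
  res$significant <- is.finite(dn$p) && dn$p < alpha && any_disjoint
  res$duncan <- dn
  class(res) <- "environment_result"
  res
}

#' Mine candidate genes across a region and environments
#'
#' For every gene: collect promoter + CDS variants, enumerate haplotypes,
#' keep major haplotypes, and test phenotype differences in each
#' environment. A gene is a candidate iff it is significant in **every**
#' environment. No multiple-testing correction is applied across genes by
#' default (set `bonferroni = TRUE` to divide alpha by the number of genes).
#'
#' @param genes List of [gene_model()] objects.
#' @param variants A [variant_set()] for the region.
#' @param phen Phenotype table.
#' @param trait Trait name (e.g. `"SL"`).
#' @param environments Character vector of environment names (>= 1).
#' @param alpha Per-test significance level (default 0.05).
#' @param min_count Major-haplotype floor (default 11).
#' @param regions Region set passed to [collect_gene_variants()].
#' @param promoter_len Promoter length in bp.
#' @param bonferroni Divide alpha by the number of genes (default FALSE).
#' @return List of `candidate_report` objects sorted by minimum omnibus p
#'   (candidates first); each has `gene_id`, `results` (per environment),
#'   `is_candidate`, `reason`.
#' @export
mine_candidates <- function(genes, variants, phen, trait, environments,
                            alpha = 0.05, min_count = 11,
                            regions = c("promoter", "cds"),
                            promoter_len = 1000, bonferroni = FALSE) {
  if (!length(environments)) stop("mine_candidates: need >= 1 environment")
  if (!length(genes)) return(list())
  a <- if (bonferroni) alpha / length(genes) else alpha
  phen <- data.table::as.data.table(phen)
  reports <- lapply(genes, function(g) {
    gvs <- collect_gene_variants(variants, g, regions = regions,
                                 promoter_len = promoter_len)
    if (nrow(gvs$sites) == 0L) {
      rep <- list(gene_id = g$gene_id, results = list(), is_candidate = FALSE,
                  reason = "no variants in selected regions")
      class(rep) <- "candidate_report"
      return(rep)
    }
    gh <- major_haplotypes(enumerate_haplotypes(gvs, g$gene_id),
                           min_count = min_count)
    results <- lapply(environments, function(env)
      test_gene(gh, phen, trait, env, alpha = a))
    names(results) <- environments
    testable <- vapply(results, `[[`, logical(1), "testable")
    sig <- vapply(results, `[[`, logical(1), "significant")
    is_cand <- all(testable) && all(sig)
    reason <- if (!all(testable)) "fewer than 2 testable major haplotypes in some environment"
      else if (is_cand) "significant haplotype differences in all environments"
      else sprintf("not significant in %d of %d environment(s)",
                   sum(!sig), length(sig))
    rep <- list(gene_id = g$gene_id, results = results,
                is_candidate = is_cand, reason = reason)
    class(rep) <- "candidate_report"
    rep
  })
  minp <- vapply(reports, function(r) {
    ps <- vapply(r$results, function(x) x$p %||% NA_real_, numeric(1))
    if (all(is.na(ps))) Inf else min(ps, na.rm = TRUE)
  }, numeric(1))
  reports[order(minp)]
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("%s: %s (%s)\n", x$gene_id,
              if (x$is_candidate) "CANDIDATE" else "not a candidate", x$reason))
  for (env in names(x$results)) {
    r <- x$results[[env]]
    cat(sprintf("  %s: %s, p = %s\n", env,
                if (!r$testable) "untestable"
                else if (r$significant) "significant" else "ns",
                format(r$p, digits = 3)))
  }
  invisible(x)
}

#' Flatten candidate reports to a table
#' @param reports Output of [mine_candidates()].
#' @return data.table with gene_id, environment, n_haplotypes, p,
#'   significant, is_candidate.
#' @export
candidate_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    if (!length(r$results))
      return(data.table::data.table(gene_id = r$gene_id, environment = NA_character_,
                                    n_haplotypes = 0L, p = NA_real_,
                                    significant = FALSE, is_candidate = r$is_candidate))
    data.table::rbindlist(lapply(r$results, function(x)
      data.table::data.table(gene_id = r$gene_id, environment = x$environment,
                             n_haplotypes = x$n_haplotypes, p = x$p,
                             significant = x$significant,
                             is_candidate = r$is_candidate)))
  })
  data.table::rbindlist(rows)
}
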