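#' Cross two genes' haplotype assignments into combination groups
#'
#' Accessions assigned in both genes are grouped by their (hapA, hapB) pair;
#' combinations realized by at least `min_count` accessions are returned,
#' ordered by (hapA, hapB). There is deliberately no "more than 10" filter
#' here — published combination tables keep cells down to n = 8 — but a small
#' floor (default 5) avoids degenerate groups in the range test.
#'
#' @param ghA,ghB `gene_haplotypes` over the same panel (typically already
#'   major-filtered).
#' @param min_count Minimum accessions per combination (default 5).
#' @return data.table with columns `combo` (label "hapA+hapB"), `hapA`,
#'   `hapB`, `n`, and list-column `accessions`.
#' @export
combine_haplotypes <- function(ghA, ghB, min_count = 5) {
  accA <- names(ghA$assignments)[!is.na(ghA$assignments)]
  accB <- names(ghB$assignments)[!is.na(ghB$assignments)]
  both <- intersect(accA, accB)
  if (!length(both)) {
    warning("combine_haplotypes: no accession assigned in both genes")
    return(data.table::data.table(combo = character(0), hapA = character(0),
                                  hapB = character(0), n = integer(0),
                                  accessions = list()))
  }
  dt <- data.table::data.table(accession = both,
                               hapA = ghA$assignments[both],
                               hapB = ghB$assignments[both])
  accession <- hapA <- hapB <- NULL # data.table NSE
  combos <- dt[, list(n = .N, accessions = list(accession)), by = c("hapA", "hapB")]
  combos <- combos[combos$n >= min_count]
  combos <- combos[order(combos$hapA, combos$hapB)]
  combos$combo <- paste0(combos$hapA, "+", combos$hapB)
  combos[, c("combo", "hapA", "hapB", "n", "accessions"), with = FALSE]
}

# Per-column stratum contrasts: within each fixed level of one gene, do the
# other gene's levels all share a compact-display letter?
stratum_contrasts <- function(dn, combos) {
  within_nonsig <- function(fix_col, vary_col) {
    lv <- unique(combos[[fix_col]])
    out <- logical(0)
    for (l in lv) {
      cc <- combos$combo[combos[[fix_col]] == l]
      if (length(cc) < 2) next
      prs <- utils::combn(cc, 2)
      for (q in seq_len(ncol(prs)))
        out[paste(fix_col, l, prs[1, q], prs[2, q], sep = "|")] <-
          shares_letter(dn, prs[1, q], prs[2, q])
    }
    out
  }
  list(within_A_strata = within_nonsig("hapA", "hapB"),  # varying B
       within_B_strata = within_nonsig("hapB", "hapA"))  # varying A
}

column_verdict <- function(contrasts) {
  a_sig <- any(!contrasts$within_B_strata)  # varying gene A matters somewhere
  b_sig <- any(!contrasts$within_A_strata)  # varying gene B matters somewhere
  if (a_sig && !b_sig) "A-dominant"
  else if (b_sig && !a_sig) "B-dominant"
  else if (a_sig && b_sig) "additive"
  else "none"
}

#' Dominance screen over two-gene haplotype combinations
#'
#' For every trait x environment column, runs [duncan_mrt()] across the
#' combination groups and evaluates within-stratum contrasts: with gene A's
#' haplotype fixed, do gene B's levels share letters (and symmetrically)?
#' The column verdict is `A-dominant` when varying A is significant in some
#' stratum while varying B never is, `B-dominant` symmetrically, `additive`
#' when both matter, `none` when neither does. The overall verdict is the
#' unanimous column verdict, or `none` when columns disagree.
#'
#' @param combos Output of [combine_haplotypes()] (>= 2 combinations).
#' @param phen Phenotype table.
#' @param columns data.frame with columns `trait`, `environment` — the
#'   trait/environment columns to screen.
#' @param alpha Significance level (default 0.05).
#' @return A `dominance_report`: list with `verdict`, `columns` (per-column
#'   verdicts), `duncan` (per-column outcomes), `contrasts`.
#' @export
dominance_screen <- function(combos, phen, columns, alpha = 0.05) {
  if (nrow(combos) < 2) stop("dominance_screen: need >= 2 combination groups")
  phen <- data.table::as.data.table(phen)
  if (!nrow(phen)) stop("dominance_screen: no trait values")
  duncans <- list(); contr <- list(); verdicts <- character(0)
  for (i in seq_len(nrow(columns))) {
    tr <- columns$trait[i]; env <- columns$environment[i]
    key <- paste(tr, env, sep = ":")
    ph <- phen[which(phen$trait == tr & phen$environment == env)]
    if (!nrow(ph)) stop("dominance_screen: no values for ", key)
    vals <- stats::setNames(ph$value, ph$accession)
    groups <- lapply(seq_len(nrow(combos)), function(j) {
      v <- vals[intersect(combos$accessions[[j]], names(vals))]
      v[is.finite(v)]
    })
    names(groups) <- combos$combo
    dn <- duncan_mrt(groups, alpha = alpha)
    duncans[[key]] <- dn
    contr[[key]] <- stratum_contrasts(dn, combos)
    verdicts[key] <- column_verdict(contr[[key]])
  }
  overall <- if (length(unique(verdicts)) == 1L) unique(verdicts) else "none"
  structure(list(verdict = overall, columns = verdicts, duncan = duncans,
                 contrasts = contr, combos = combos),
            class = "dominance_report")
}

#' Dominance screen from published summary statistics
#'
#' Same contrasts and verdict logic as [dominance_screen()], but each column
#' is supplied as printed group summaries (one row per combination: n, mean,
#' sd), so a published combination table can be re-analyzed directly.
#'
#' @param combos data.frame with columns `combo`, `hapA`, `hapB` naming the
#'   combinations.
#' @param summary_columns Named list of data.frames (label, n, mean, sd);
#'   labels must match `combos$combo`.
#' @param alpha Significance level.
#' @return A `dominance_report` (see [dominance_screen()]).
#' @export
dominance_screen_summary <- function(combos, summary_columns, alpha = 0.05) {
  combos <- data.table::as.data.table(combos)
  if (nrow(combos) < 2) stop("dominance_screen_summary: need >= 2 combinations")
  duncans <- list(); contr <- list(); verdicts <- character(0)
  for (key in names(summary_columns)) {
    gs <- summary_columns[[key]]
    if (!all(combos$combo %in% gs$label))
      stop("summary column ", key, " missing combination labels")
    dn <- duncan_mrt(gs, alpha = alpha)
    duncans[[key]] <- dn
    contr[[key]] <- stratum_contrasts(dn, combos)
    verdicts[key] <- column_verdict(contr[[key]])
  }
  overall <- if (length(unique(verdicts)) == 1L) unique(verdicts) else "none"
  structure(list(verdict = overall, columns = verdicts, duncan = duncans,
                 contrasts = contr, combos = combos),
            class = "dominance_report")
}

#' @export
print.dominance_report <- function(x, ...) {
  cat("dominance screen verdict:", x$verdict, "\n")
  for (key in names(x$columns)) {
    tab <- x$duncan[[key]]$table
    cat(sprintf("  %s (%s): %s\n", key, x$columns[[key]],
                paste(sprintf("%s=%s", tab$label, tab$letter), collapse = " ")))
  }
  invisible(x)
}
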