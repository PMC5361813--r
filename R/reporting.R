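#' Format a count ratio as a percentage string
#'
#' Rounds to nearest (ties away from zero) at the requested precision and
#' suffixes `%`.
#'
#' @param numerator,denominator counts; `denominator > 0`.
#' @param decimals non-negative number of decimal places.
#' @return character percentage, e.g. `"47.6%"`.
#' @export
format_rate <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  stopifnot(decimals >= 0)
  pct <- round_half_up(100 * numerator / denominator, decimals)
  sprintf(paste0("%.", decimals, "f%%"), pct)
}

# round half away from zero (base round() is half-to-even)
#' @noRd
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Summarize diagnostic yield over a family-outcome table
#'
#' Counts families per finding category and computes rates overall, by family
#' structure and by phenotype group. Categories: `known_gene` (established
#' disease gene), `novel_gene` (gene implicated in more than one family),
#' `candidate_gene` (variant seen in a single family), `unsolved`. A family
#' counts as having a potential molecular diagnosis when its category is any
#' of the first three; the stricter known/novel rate excludes candidates.
#'
#' @param outcomes data.frame with one row per family: `family_id`,
#'   `structure` (`trio`, `quartet`, `multiplex`, `singleton`),
#'   `phenotype_group`, `category`, and optional logical
#'   `independently_solved` (re-solved by the clinical laboratory's own
#'   reanalysis; meaningful for known/novel families).
#' @return an object of class `yield_report`.
#' @export
summarize_yield <- function(outcomes) {
  valid <- c("known_gene", "novel_gene", "candidate_gene", "unsolved")
  bad <- setdiff(unique(outcomes$category), valid)
  if (length(bad)) stop("unknown category label: ", paste(bad, collapse = ", "))
  n <- nrow(outcomes)
  cat_counts <- table(factor(outcomes$category, levels = valid))
  solved <- outcomes$category != "unsolved"
  known_novel <- outcomes$category %in% c("known_gene", "novel_gene")
  by_group <- function(grp) {
    lv <- unique(grp)
    data.frame(group = lv,
               n = vapply(lv, function(g) sum(grp == g), 0L),
               n_solved = vapply(lv, function(g) sum(solved & grp == g), 0L),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  add_rate <- function(d) {
    d$rate_pct <- round_half_up(100 * d$n_solved / d$n, 1)
    d$rate <- format_rate(d$n_solved, d$n, 1)
    d
  }
  structure_tab <- add_rate(by_group(outcomes$structure))
  phenotype_tab <- add_rate(by_group(outcomes$phenotype_group))
  ind <- if ("independently_solved" %in% names(outcomes))
    sum(outcomes$independently_solved & known_novel, na.rm = TRUE)
  else NA_integer_
  rep <- list(
    n_families = n,
    category_counts = as.integer(cat_counts),
    categories = stats::setNames(as.integer(cat_counts), valid),
    overall = list(
      known_novel_n = sum(known_novel),
      known_novel_pct = round_half_up(100 * sum(known_novel) / n, 0),
      candidate_n = sum(outcomes$category == "candidate_gene"),
      candidate_pct = round_half_up(
        100 * sum(outcomes$category == "candidate_gene") / n, 0),
      solved_n = sum(solved),
      solved_pct = round_half_up(100 * sum(solved) / n, 0)),
    by_structure = structure_tab,
    by_phenotype = phenotype_tab,
    independently_solved = list(
      n = ind, of = sum(known_novel),
      pct = if (is.na(ind)) NA_real_
            else round_half_up(100 * ind / sum(known_novel), 1)))
  class(rep) <- "yield_report"
  rep
}

#' @export
print.yield_report <- function(x, ...) {
  cat("Diagnostic yield over", x$n_families, "families\n")
  cat(sprintf("  known/novel gene: %d (%s)\n", x$overall$known_novel_n,
              format_rate(x$overall$known_novel_n, x$n_families, 0)))
  cat(sprintf("  incl. candidate genes: %d (%s)\n", x$overall$solved_n,
              format_rate(x$overall$solved_n, x$n_families, 0)))
  cat("  by structure:\n")
  for (i in seq_len(nrow(x$by_structure)))
    cat(sprintf("    %-10s %d/%d (%s)\n", x$by_structure$group[i],
                x$by_structure$n_solved[i], x$by_structure$n[i],
                x$by_structure$rate[i]))
  cat("  by phenotype group:\n")
  for (i in seq_len(nrow(x$by_phenotype)))
    cat(sprintf("    %-10s %d/%d (%s)\n", x$by_phenotype$group[i],
                x$by_phenotype$n_solved[i], x$by_phenotype$n[i],
                x$by_phenotype$rate[i]))
  if (!is.na(x$independently_solved$n))
    cat(sprintf("  independently re-solved known/novel: %d/%d (%s)\n",
                x$independently_solved$n, x$independently_solved$of,
                format_rate(x$independently_solved$n,
                            x$independently_solved$of, 1)))
  invisible(x)
}

#' Project the combined diagnostic yield
#'
#' Combines a first-pass clinical yield with the residual research yield on
#' the unsolved remainder: `combined = initial + (1 - initial) * residual`
#' (equivalently `1 - (1 - initial)(1 - residual)`).
#'
#' @param initial_rate first-pass diagnostic rate, in \[0, 1\].
#' @param residual_rate yield of reanalysis among initially unsolved cases.
#' @return object of class `yield_projection` with `initial_rate`,
#'   `residual_rate`, `combined_rate`.
#' @export
project_overall_yield <- function(initial_rate, residual_rate) {
  if (any(c(initial_rate, residual_rate) < 0) ||
      any(c(initial_rate, residual_rate) > 1))
    stop("rates must lie in [0, 1]")
  combined <- initial_rate + (1 - initial_rate) * residual_rate
  structure(list(initial_rate = initial_rate, residual_rate = residual_rate,
                 combined_rate = combined),
            class = "yield_projection")
}

#' @export
print.yield_projection <- function(x, ...) {
  cat(sprintf("combined yield: %.1f%% + (1 - %.1f%%) x %.1f%% = %s\n",
              100 * x$initial_rate, 100 * x$initial_rate,
              100 * x$residual_rate,
              format_rate(x$combined_rate * 1000, 1000, 0)))
  invisible(x)
}

#' Annotate heterozygous SNV candidates with trans deletion evidence
#'
#' A heterozygous candidate SNV plus an overlapping-gene dropout deletion in
#' the same proband is a potential compound of an SNV and a CNV in trans; the
#' candidate gains annotation `possible_compound_SNV_del` with the deletion
#' span. Homozygous candidates are left unannotated (not a trans
#' configuration).
#'
#' @param candidates candidate data.frame (needs `sample_id`, `gene`, `gt`).
#' @param deletions deletion calls from [call_dropout_deletions()].
#' @return `candidates` with added `trans_deletion` and `deletion_span`
#'   columns.
#' @export
join_snv_deletion_trans <- function(candidates, deletions) {
  candidates$trans_deletion <- rep(NA_character_, nrow(candidates))
  candidates$deletion_span <- rep(NA_character_, nrow(candidates))
  if (!nrow(candidates) || !nrow(deletions)) return(candidates)
  key_c <- paste(candidates$sample_id, candidates$gene)
  key_d <- paste(deletions$sample_id, deletions$gene)
  hit <- match(key_c, key_d)
  het <- candidates$gt %in% "het"
  sel <- het & !is.na(hit)
  candidates$trans_deletion[sel] <- "possible_compound_SNV_del"
  candidates$deletion_span[sel] <- sprintf(
    "exons %d-%d", deletions$start_index[hit[sel]],
    deletions$end_index[hit[sel]])
  candidates
}

#' Bundled example outcome table: a 74-family reanalysis pilot cohort
#'
#' A deterministic family-outcome fixture for a cohort of 74 unsolved
#' clinical exome cases re-analyzed in a research setting: 63 trios (30 with
#' a potential molecular diagnosis), 4 quartets (3 solved), 1 multiplex
#' family with three affected siblings (solved) and 6 singletons (4 solved);
#' 27 families solved by a known or novel disease gene (12 of them later
#' re-solved independently by the clinical laboratory's own reanalysis) and
#' 11 by a candidate gene; 59 families in the developmental-delay /
#' intellectual-disability (DD/ID) phenotype group (32 solved), 14 outside
#' it (6 solved) and one unclassified. Joint cells not determined by these
#' marginal counts are filled deterministically; only marginal rates are
#' meaningful.
#'
#' @return data.frame with columns `family_id`, `structure`,
#'   `phenotype_group`, `category`, `independently_solved`.
#' @export
pilot_outcomes <- function() {
  fam <- data.frame(
    family_id = c(sprintf("T%02d", 1:63), sprintf("Q%d", 1:4), "M1",
                  sprintf("S%d", 1:6)),
    structure = c(rep("trio", 63), rep("quartet", 4), "multiplex",
                  rep("singleton", 6)),
    stringsAsFactors = FALSE)
  solved <- c(rep(TRUE, 30), rep(FALSE, 33),      # trios: 30/63
              rep(TRUE, 3), FALSE,                # quartets: 3/4
              TRUE,                               # multiplex: 1/1
              rep(TRUE, 4), rep(FALSE, 2))        # singletons: 4/6
  # categories among the 38 solved families: 23 known + 4 novel = 27
  # known/novel, then 11 candidate
  cat_seq <- c(rep("known_gene", 23), rep("novel_gene", 4),
               rep("candidate_gene", 11))
  fam$category <- "unsolved"
  fam$category[solved] <- cat_seq
  # phenotype groups: 59 DD/ID (32 solved), 14 non-DD/ID (6 solved), 1 other
  fam$phenotype_group <- NA_character_
  fam$phenotype_group[solved] <- c(rep("DD/ID", 32), rep("non-DD/ID", 6))
  fam$phenotype_group[!solved] <- c(rep("DD/ID", 27), rep("non-DD/ID", 8),
                                    "other")
  # 12 of the 27 known/novel families were re-solved independently
  kn <- which(fam$category %in% c("known_gene", "novel_gene"))
  fam$independently_solved <- FALSE
  fam$independently_solved[kn[1:12]] <- TRUE
  fam
}
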