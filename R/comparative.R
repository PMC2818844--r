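#' Cross-sample overlap, X-linkage and expression statistics
#'
#' Set-level statistics over promoter classes: pairwise overlap with
#' sharing fractions and Fisher's exact test, three-way Venn counts,
#' X-chromosome fold enrichment, and integration of binary single-cell
#' expression calls (a gene is "present" when detected in at least half
#' of the profiled cells, 10 of 20 by default).
#'
#' @name comparative
NULL

#' Pairwise overlap of two promoter sets
#'
#' @param set_a,set_b Character vectors of promoter ids.
#' @param universe Character vector: all promoters on the array.
#' @return One-row tibble: 2x2 contingency counts `a` (in both), `b` (A
#'   only), `c` (B only), `d` (neither), set sizes, sharing fractions
#'   `|A∩B|/|A|` and `|A∩B|/|B|` (`NA` when the denominator set is
#'   empty), and the two-sided Fisher p-value on the universe.
#' @export
overlap_counts <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  out_of <- c(setdiff(set_a, universe), setdiff(set_b, universe))
  if (length(out_of) > 0) {
    abort(sprintf("element(s) outside universe: %s",
                  paste(utils::head(out_of, 5), collapse = ", ")))
  }
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  cc <- length(setdiff(set_b, set_a))
  d <- length(universe) - a - b - cc
  tibble(a = a, b = b, c = cc, d = d,
         n_a = a + b, n_b = a + cc, n_intersect = a,
         sharing_a = if (a + b > 0) a / (a + b) else NA_real_,
         sharing_b = if (a + cc > 0) a / (a + cc) else NA_real_,
         fisher_p = fisher_exact(matrix(c(a, b, cc, d), 2, byrow = TRUE)))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities of
#' all tables with the observed margins whose probability does not
#' exceed that of the observed table (the conventional probability-mass
#' rule). Tables with a zero margin return p = 1 with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   `rbind(c(a, b), c(c, d))`, or a length-4 vector `(a, b, c, d)`.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(table) {
  x <- as.integer(round(as.vector(t(as.matrix(table)))))
  if (length(x) != 4 || any(is.na(x)) || any(x < 0)) {
    abort("fisher_exact needs a 2x2 table of non-negative counts")
  }
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  if (a + b + cc + d == 0) abort("fisher_exact: table total must be > 0")
  m <- a + b; n2 <- cc + d; k <- a + cc
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) {
    warn("fisher_exact: zero margin; p = 1 by convention")
    return(1)
  }
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' X-linked fold enrichment of a promoter set
#'
#' Frequency of the target among X-chromosome promoters divided by its
#' frequency among all other promoters.
#'
#' @param target_set Character vector of promoter ids.
#' @param promoters A `promoter_set` tibble (its `x_chrom` attribute
#'   designates the X chromosome).
#' @return The fold enrichment (0 when the target misses X entirely).
#' @export
x_linked_fold <- function(target_set, promoters) {
  x_chrom <- attr(promoters, "x_chrom") %||% "chrX"
  on_x <- promoters$promoter_id[promoters$chrom == x_chrom]
  off_x <- promoters$promoter_id[promoters$chrom != x_chrom]
  if (length(on_x) == 0 || length(off_x) == 0) {
    abort("need at least one promoter on and off the X chromosome")
  }
  fx <- length(intersect(target_set, on_x)) / length(on_x)
  fo <- length(intersect(target_set, off_x)) / length(off_x)
  if (fo == 0) {
    abort("off-X target frequency is zero: fold enrichment is infinite")
  }
  fx / fo
}

#' Present/absent call from single-cell detections
#'
#' A gene is "present" when detected in at least `min_present` of the
#' profiled cells; by default at least half of them (10 of 20).
#'
#' @param detections Binary vector of per-cell detection calls.
#' @param min_present Detection count threshold; default
#'   `ceiling(length(detections) / 2)`.
#' @param n_cells Expected number of cells (default: length of
#'   `detections`); a mismatch is an error.
#' @return Logical present call.
#' @export
present_call <- function(detections, min_present = NULL, n_cells = NULL) {
  if (!is.null(n_cells) && length(detections) != n_cells) {
    abort(sprintf("expected %d cells, got %d detections", n_cells,
                  length(detections)))
  }
  if (!all(detections %in% c(0, 1))) {
    abort("detections must be binary (0/1)")
  }
  if (is.null(min_present)) min_present <- ceiling(length(detections) / 2)
  sum(detections) >= min_present
}

#' Present calls for a whole expression matrix
#'
#' @param expression Tibble with `promoter_id` plus one binary column
#'   per cell, as from [simulate_expression()].
#' @param min_present Detection threshold; default: at least half the
#'   cells.
#' @return Tibble `promoter_id`, `present`.
#' @export
present_calls <- function(expression, min_present = NULL) {
  .stop_if_not_cols(expression, "promoter_id", "expression matrix")
  mat <- as.matrix(expression[, setdiff(names(expression), "promoter_id")])
  if (is.null(min_present)) min_present <- ceiling(ncol(mat) / 2)
  tibble(promoter_id = expression$promoter_id,
         present = rowSums(mat) >= min_present)
}

#' Percent of expressed genes per chromatin class
#'
#' @param records Tibble with columns `promoter_id`, `state` (e.g. a
#'   `promoter_states` table or truth states).
#' @param presence Tibble with columns `promoter_id`, `present`, over
#'   the same promoter universe.
#' @return Tibble `state`, `n`, `n_present`, `percent_expressed`
#'   (`NA` for states with no members), one row per state
#'   none/K4/K27/bivalent.
#' @export
percent_expressed_by_class <- function(records, presence) {
  .stop_if_not_cols(records, c("promoter_id", "state"), "records")
  .stop_if_not_cols(presence, c("promoter_id", "present"), "presence")
  if (!setequal(records$promoter_id, presence$promoter_id)) {
    abort("promoter universe mismatch between records and presence")
  }
  dplyr::left_join(as_tibble(records), as_tibble(presence), by = "promoter_id") |>
    dplyr::mutate(state = factor(.data$state, levels = .STATES)) |>
    dplyr::group_by(.data$state, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(), n_present = sum(.data$present),
                     .groups = "drop") |>
    dplyr::mutate(percent_expressed = ifelse(.data$n > 0,
                                             100 * .data$n_present / .data$n,
                                             NA_real_),
                  state = as.character(.data$state))
}

#' Three-way Venn counts
#'
#' @param set_a,set_b,set_c Character vectors over one universe.
#' @param labels Names for the three sets (default A, B, C).
#' @return Tibble with one row per Venn region (`A_only`, `B_only`,
#'   `C_only`, `AB`, `AC`, `BC`, `ABC`) and its count; region counts sum
#'   to `|A ∪ B ∪ C|`.
#' @export
three_way_overlap <- function(set_a, set_b, set_c, labels = c("A", "B", "C")) {
  u <- unique(c(set_a, set_b, set_c))
  ina <- u %in% set_a; inb <- u %in% set_b; inc <- u %in% set_c
  region <- paste0(ifelse(ina, "A", ""), ifelse(inb, "B", ""), ifelse(inc, "C", ""))
  all_regions <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  counts <- vapply(all_regions, function(r) sum(region == r), integer(1))
  tibble(region = c("A_only", "B_only", "C_only", "AB", "AC", "BC", "ABC"),
         set_a = labels[1], set_b = labels[2], set_c = labels[3],
         count = unname(counts))
}
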