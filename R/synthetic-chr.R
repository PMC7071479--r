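#' Configuration for a synthetic chromogenic scoring cohort
#'
#' The chromogenic arm is simulated at the score level: each virtual
#' neuron receives an ordinal DAB intensity score in {0, 1+, 2+, 3+}
#' drawn i.i.d. from `score_probabilities`. Defaults follow the study
#' sampling design of 10 random 400x fields per case with roughly 30
#' assessable neurons each (field density is not fixed by the design
#' and is configurable).
#'
#' @param n_cases Number of cases.
#' @param neurons_per_case Neurons scored per case (spread over
#'   `n_fields` fields).
#' @param score_probabilities Length-4 probability vector over scores
#'   0:3; must be nonnegative and sum to 1 (tolerance 1e-9).
#' @param n_fields Fields per case (default 10).
#' @param seed Integer RNG seed.
#' @return An object of class `chr_sim_config`.
#' @export
chr_sim_config <- function(n_cases, neurons_per_case = 300L,
                           score_probabilities, n_fields = 10L,
                           seed = 1L) {
  if (!is.numeric(score_probabilities) || length(score_probabilities) != 4L)
    stop_fq("'score_probabilities' must be a length-4 numeric vector")
  if (any(score_probabilities < 0))
    stop_fq("'score_probabilities' must be nonnegative")
  if (abs(sum(score_probabilities) - 1) > 1e-9)
    stop_fq("'score_probabilities' must sum to 1")
  structure(list(
    n_cases = check_count(n_cases, "n_cases", 1L),
    neurons_per_case = check_count(neurons_per_case, "neurons_per_case", 1L),
    score_probabilities = as.numeric(score_probabilities),
    n_fields = check_count(n_fields, "n_fields", 1L),
    seed = check_count(seed, "seed")), class = "chr_sim_config")
}

#' Generate a per-neuron chromogenic score table
#'
#' @param config A [chr_sim_config()].
#' @param case_prefix Prefix for generated case ids.
#' @return Data frame with columns `case_id`, `field_id` (1-based),
#'   `score` (integer 0-3); deterministic given the config seed.
#' @examples
#' generate_chr_cohort(chr_sim_config(2, 10, c(0, 0, 0, 1), seed = 1))
#' @export
generate_chr_cohort <- function(config, case_prefix = "case") {
  stopifnot(inherits(config, "chr_sim_config"))
  with_preserved_rng(config$seed, {
    m <- config$neurons_per_case
    fields <- sort(rep(seq_len(config$n_fields), length.out = m))
    out <- lapply(seq_len(config$n_cases), function(i) {
      data.frame(case_id = sprintf("%s%02d", case_prefix, i),
                 field_id = fields,
                 score = sample(0:3, m, replace = TRUE,
                                prob = config$score_probabilities))
    })
    do.call(rbind, out)
  })
}

#' Printed per-group ranges of case mean scores
#'
#' The per-case average LMTK2 labelling intensities reported for the
#' four groups: 2.13-2.92 (early MFG, the NFT-spared control),
#' 1.07-1.70 (early aHPC), 1.22-1.81 (late MFG) and 1.00-1.55
#' (late aHPC).
#'
#' @return Data frame with columns `group`, `lo`, `hi`.
#' @export
chr_group_ranges <- function() {
  data.frame(group = .group_levels,
             lo = c(2.13, 1.07, 1.22, 1.00),
             hi = c(2.92, 1.70, 1.81, 1.55))
}

#' Generate a multi-group cohort with case means spanning given ranges
#'
#' For each group, per-case target mean scores are drawn by stratified
#' sampling over the group's `[lo, hi]` range (one draw per equal
#' subinterval), so the realized case means span the range by
#' construction. Each case's neurons are then drawn i.i.d. from the
#' two-point distribution on the adjacent integer scores bracketing the
#' target (e.g. a target of 2.4 mixes 60% 2+ with 40% 3+), whose
#' expectation is exactly the target.
#'
#' @param ranges Data frame `group`, `lo`, `hi` (default
#'   [chr_group_ranges()]); means must lie in \[0, 3\].
#' @param n_cases_per_group Cases per group (default 5, the study's
#'   group size).
#' @param neurons_per_case Neurons per case (default 300).
#' @param n_fields Fields per case (default 10).
#' @param seed Integer RNG seed.
#' @return List with `scores` (per-neuron table: `case_id`, `group`,
#'   `field_id`, `score`) and `cases` (per-case table: `case_id`,
#'   `group`, `region`, `stage`, `target_mean`).
#' @export
generate_chr_group_cohort <- function(ranges = chr_group_ranges(),
                                      n_cases_per_group = 5L,
                                      neurons_per_case = 300L,
                                      n_fields = 10L,
                                      seed = 1L) {
  stopifnot(is.data.frame(ranges),
            all(c("group", "lo", "hi") %in% names(ranges)))
  if (any(ranges$lo < 0 | ranges$hi > 3 | ranges$lo > ranges$hi))
    stop_fq("'ranges' must satisfy 0 <= lo <= hi <= 3")
  n_cases_per_group <- check_count(n_cases_per_group, "n_cases_per_group", 2L)
  neurons_per_case <- check_count(neurons_per_case, "neurons_per_case", 1L)
  with_preserved_rng(seed, {
    scores <- list(); cases <- list()
    for (gi in seq_len(nrow(ranges))) {
      g <- ranges$group[gi]
      parts <- strsplit(g, "_", fixed = TRUE)[[1]]
      width <- (ranges$hi[gi] - ranges$lo[gi]) / n_cases_per_group
      targets <- ranges$lo[gi] + (seq_len(n_cases_per_group) - 1 +
                                    runif(n_cases_per_group)) * width
      for (ci in seq_len(n_cases_per_group)) {
        case_id <- sprintf("%s_case%02d", g, ci)
        sc <- r_two_point_scores(neurons_per_case, targets[ci])
        fields <- rep(seq_len(n_fields), length.out = neurons_per_case)
        scores[[length(scores) + 1L]] <-
          data.frame(case_id = case_id, group = g,
                     field_id = sort(fields), score = sc)
        cases[[length(cases) + 1L]] <-
          data.frame(case_id = case_id, group = g, stage = parts[1],
                     region = parts[2], target_mean = targets[ci])
      }
    }
    list(scores = do.call(rbind, scores), cases = do.call(rbind, cases))
  })
}

# n i.i.d. integer scores from the two-point distribution on
# {floor(m), floor(m)+1} with mean m.
r_two_point_scores <- function(n, m) {
  k <- min(floor(m), 2)
  frac <- m - k
  k + (runif(n) < frac)
}
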