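#' Map a mean optical density to a 0-3+ score
#'
#' The semiquantitative DAB scale is ordinarily assigned by eye; this
#' helper supports an intensity-driven path with user-chosen cut
#' points. The score is the number of cut points *strictly below* the
#' measured density, so a value equal to a cut point takes the lower
#' score.
#'
#' @param mean_od Numeric vector of per-neuron mean optical densities.
#' @param cut_points Three strictly ascending numeric cut points.
#' @return Integer scores in 0:3.
#' @examples
#' score_from_intensity(c(10, 60, 100, 250), cut_points = c(60, 120, 180))
#' @export
score_from_intensity <- function(mean_od, cut_points) {
  if (!is.numeric(cut_points) || length(cut_points) != 3L ||
      any(diff(cut_points) <= 0))
    stop_fq("'cut_points' must be three strictly ascending numbers")
  if (!is.numeric(mean_od) || anyNA(mean_od))
    stop_fq("'mean_od' must be numeric without NA")
  vapply(mean_od, function(v) sum(cut_points < v), integer(1))
}

#' Per-case mean labelling intensity score
#'
#' @param scores Integer vector of per-neuron scores in 0:3, or a data
#'   frame with a `score` column.
#' @return Arithmetic mean score (in \[0, 3\]).
#' @export
case_mean_score <- function(scores) {
  if (is.data.frame(scores)) scores <- scores$score
  if (length(scores) == 0) stop_fq("case has no scored neurons")
  if (anyNA(scores) || any(!scores %in% 0:3))
    stop_fq("scores must be integers in 0:3")
  mean(scores)
}

#' Per-case mean scores for a neuron score table
#'
#' @param score_table Data frame with columns `case_id` and `score`
#'   (e.g. from [generate_chr_cohort()] or [read_neuron_scores()]).
#' @return Data frame `case_id`, `mean_score`, `n_neurons`, ordered by
#'   first appearance of each case.
#' @export
case_mean_scores <- function(score_table) {
  stopifnot(is.data.frame(score_table),
            all(c("case_id", "score") %in% names(score_table)))
  ids <- unique(score_table$case_id)
  out <- lapply(ids, function(id) {
    sc <- score_table$score[score_table$case_id == id]
    data.frame(case_id = id, mean_score = case_mean_score(sc),
               n_neurons = length(sc))
  })
  do.call(rbind, out)
}

#' Group mean of case mean scores
#'
#' Group means are unweighted means of per-case averages (case first,
#' then group), so cases with unequal neuron counts contribute equally.
#'
#' @param case_table Data frame with columns `mean_score` and `group`.
#' @param group Group label to summarize.
#' @return The group mean score.
#' @export
group_mean_score <- function(case_table, group) {
  stopifnot(is.data.frame(case_table),
            all(c("mean_score", "group") %in% names(case_table)))
  m <- case_table$mean_score[case_table$group == group]
  if (length(m) == 0) stop_fq(sprintf("no cases in group '%s'", group))
  mean(m)
}

#' Read a per-neuron score CSV
#'
#' Two input shapes are accepted: pre-scored observations (columns
#' `case_id`, `field_id`, `score`) — the primary path — or raw
#' densities (`case_id`, `field_id`, `mean_od`) which are converted
#' through [score_from_intensity()] with the supplied cut points.
#'
#' @param path CSV path.
#' @param cut_points Required iff the file carries `mean_od` instead
#'   of `score`.
#' @return Data frame `case_id`, `field_id`, `score`.
#' @export
read_neuron_scores <- function(path, cut_points = NULL) {
  tab <- read_table(path)
  if (!all(c("case_id", "field_id") %in% names(tab)))
    stop_fq("score table needs columns 'case_id' and 'field_id'")
  if ("score" %in% names(tab)) {
    if (anyNA(tab$score) || any(!tab$score %in% 0:3))
      stop_fq("'score' column must hold integers in 0:3")
    return(tab[c("case_id", "field_id", "score")])
  }
  if (!"mean_od" %in% names(tab))
    stop_fq("score table needs a 'score' or 'mean_od' column")
  if (is.null(cut_points))
    stop_fq("'cut_points' required to score a 'mean_od' table")
  tab$score <- score_from_intensity(tab$mean_od, cut_points)
  tab[c("case_id", "field_id", "score")]
}

#' Case metadata of the study cohort
#'
#' Loads the per-patient metadata table shipped with the package
#' (study id, sex, age at baseline, final MMSE, Braak tau stage, APOE
#' genotype) for the ten autopsy cases of the design: five with early
#' (Braak I-III) and five with late (Braak VI) tau pathology. One case
#' has no APOE genotype on record (empty field).
#'
#' @return Data frame with columns `case_id`, `sex`, `age`,
#'   `final_mmse`, `braak_stage`, `apoe`, `stage` (early/late derived
#'   from the Braak stage).
#' @export
cohort_metadata <- function() {
  path <- system.file("extdata", "cohort_metadata.csv",
                      package = "fdlquant", mustWork = TRUE)
  tab <- read_table(path)
  tab$stage <- ifelse(tab$braak_stage == "VI", "late", "early")
  tab
}
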