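#' Published demographic and questionnaire summaries of the emulated study
#'
#' Per-group means, standard deviations and sizes for age and the
#' questionnaire scores (EQ, ASQ, BDI, STAI, PANAS) of the two-group
#' pharmaco-fMRI study the synthetic generator emulates, together with the
#' t and p values printed alongside them. These summaries serve as worked
#' examples for [summary_t()]: the printed t-values are reproduced from the
#' summaries by the Welch form to within rounding.
#'
#' @return data.frame, one row per variable.
#' @export
#' @examples
#' d <- study_demographics()
#' row <- d[d$variable == "BDI", ]
#' summary_t(row$mean_treatment, row$sd_treatment, row$n_treatment,
#'           row$mean_control, row$sd_control, row$n_control)$t
study_demographics <- function() {
  utils::read.delim(
    system.file("extdata", "demographics_summary.tsv", package = "netsweep"),
    stringsAsFactors = FALSE
  )
}

#' Study sample accounting
#'
#' Recruited and excluded participant counts of the emulated study; the
#' analyzed sample size is their difference.
#'
#' @return List with `recruited`, `excluded`, `analyzed`.
#' @export
#' @examples
#' study_sample_accounting()$analyzed  # 139
study_sample_accounting <- function() {
  df <- utils::read.delim(
    system.file("extdata", "sample_accounting.tsv", package = "netsweep"),
    stringsAsFactors = FALSE
  )
  recruited <- df$count[df$stage == "recruited"]
  excluded <- df$count[df$stage == "excluded"]
  list(recruited = recruited, excluded = excluded,
       analyzed = recruited - excluded)
}

#' Recompute the printed t statistics from the demographic summaries
#'
#' Applies [summary_t()] to every row of [study_demographics()] and
#' reports the computed Welch t next to the printed value.
#'
#' @param var_equal pooled-variance form if `TRUE`.
#' @return data.frame: `variable`, `t_computed`, `t_printed`,
#'   `abs_difference`.
#' @export
demographics_t_table <- function(var_equal = FALSE) {
  d <- study_demographics()
  t_computed <- vapply(seq_len(nrow(d)), function(i) {
    summary_t(d$mean_treatment[i], d$sd_treatment[i], d$n_treatment[i],
              d$mean_control[i], d$sd_control[i], d$n_control[i],
              var_equal = var_equal)$t
  }, numeric(1))
  data.frame(
    variable = d$variable,
    t_computed = t_computed,
    t_printed = d$t_printed,
    abs_difference = abs(t_computed - d$t_printed),
    stringsAsFactors = FALSE
  )
}
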