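#' Printed summary tables of an example monochorionic-twin sFGR cohort
#'
#' Summary rows for an example cohort of 23 monochorionic twin pregnancies
#' with selective fetal growth restriction (sFGR) and 32 uncomplicated
#' controls, as printed in clinical comparison tables: birth-weight
#' `(mean, SD, n)` triples for the larger and smaller twin of each group,
#' 2x2 count pairs of general maternal conditions, and the
#' count-(percent) cells for arteriovenous anastomosis presence. These
#' printed summaries are the inputs of the summary-statistics operations
#' ([t_from_summary()], [proportion_pct()], [fisher_exact_or_chisq()]).
#'
#' @return A named list of tibbles: `birthweight` (`group`, `fetus`,
#'   `mean_g`, `sd_g`, `n`), `general_conditions` (`condition`,
#'   `sfgr_count`, `sfgr_n`, `control_count`, `control_n`) and
#'   `av_anastomosis` (`group`, `count`, `n`).
#' @export
#' @examples
#' tabs <- twin_cohort_tables()
#' with(tabs$birthweight[tabs$birthweight$group == "sFGR", ],
#'      t_from_summary(mean_g[1], sd_g[1], n[1], mean_g[2], sd_g[2], n[2]))
twin_cohort_tables <- function() {
  list(
    birthweight = tibble(
      group = c("sFGR", "sFGR", "control", "control"),
      fetus = c("larger", "smaller", "larger", "smaller"),
      mean_g = c(2119, 1444, 2362, 2112),
      sd_g = c(454, 350, 546, 553),
      n = c(23, 23, 32, 32)
    ),
    general_conditions = tibble(
      condition = c("senile_parturient", "multiparous",
                    "assisted_reproduction", "early_fetal_reduction",
                    "hypertension"),
      sfgr_count = c(1, 2, 2, 0, 3),
      sfgr_n = 23,
      control_count = c(3, 7, 8, 1, 3),
      control_n = 32
    ),
    av_anastomosis = tibble(
      group = c("sFGR", "control"),
      count = c(19, 23),
      n = c(23, 32)
    )
  )
}
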