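#' Published group summary statistics for the deficit / non-deficit sample
#'
#' Per-variable group means and dispersions for the two-group sample of 161
#' chronic male schizophrenia inpatients (70 deficit-syndrome, 91
#' non-deficit) that the synthetic generator emulates: four demographic
#' variables, the 13 negative-symptom items (0-6 ratings), the scale total,
#' four cognitive-domain scores and the social-function total (0-48, higher =
#' better). For the 13 item rows the published dispersion is a standard error
#' of the mean (`disp_kind = "se"`); everywhere else it is a standard
#' deviation. These summaries are inputs — e.g. to [welch_t()] or
#' [default_spec()] — not quantities the package computes.
#'
#' @return A `data.frame` with columns `variable`, `mean_ds`, `disp_ds`,
#'   `mean_nds`, `disp_nds`, `disp_kind`, `n_ds`, `n_nds`.
#' @export
reference_group_summaries <- function() {
  df <- read.csv(
    system.file("extdata", "group_summary_reference.csv",
                package = "symptomnet"),
    stringsAsFactors = FALSE
  )
  df$n_ds <- 70L
  df$n_nds <- 91L
  df
}

# Dispersion as an SD on both groups' scale: SE rows are rescaled by sqrt(n).
reference_sds <- function(summaries = reference_group_summaries()) {
  sd_ds <- ifelse(summaries$disp_kind == "se",
                  summaries$disp_ds * sqrt(summaries$n_ds),
                  summaries$disp_ds)
  sd_nds <- ifelse(summaries$disp_kind == "se",
                   summaries$disp_nds * sqrt(summaries$n_nds),
                   summaries$disp_nds)
  data.frame(variable = summaries$variable, sd_ds = sd_ds, sd_nds = sd_nds,
             stringsAsFactors = FALSE)
}
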