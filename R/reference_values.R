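#' Published benchmark values for the visual-imagery classification task
#'
#' Reference numbers reported for the original 18-subject static-vs-moving
#' visual-imagery EEG experiment that this package's pipeline models, kept
#' here for arithmetic consistency checks and report comparisons. The raw
#' recordings behind them are not publicly deposited, so these summaries are
#' the only quantitative anchor: per-IMF variance contribution rates and
#' correlations used for IMF screening, the per-method accuracy summaries
#' (mean with standard error, maximum, minimum, in percent), and the
#' accuracies of earlier visual-imagery BCI studies used for cross-study
#' comparison.
#'
#' @format A list with elements:
#' \describe{
#'   \item{imf_contribution_pct}{Variance contribution rate per IMF 1..8, %.}
#'   \item{imf_correlation}{Correlation of each IMF with the raw signal.}
#'   \item{accuracy}{Data frame: method, average, se, maximum, minimum (%).}
#'   \item{prior_studies}{Named numeric: reported accuracies (%) of earlier
#'     visual-imagery BCI studies.}
#' }
#' @export
vi_reference <- list(
  imf_contribution_pct = c(57.1652, 17.5349, 14.1053, 7.3225,
                           1.4372, 1.0732, 0.7628, 0.5989),
  imf_correlation = c(0.7526, 0.4932, 0.4021, 0.2136,
                      0.0034, 0.0023, 0.0013, 0.0006),
  accuracy = data.frame(
    method = c("hht", "ar", "emdar"),
    average = c(68.14, 56.29, 78.40),
    se = c(3.06, 2.73, 2.07),
    maximum = c(78.33, 71.67, 87),
    minimum = c(53.33, 30, 48.33),
    stringsAsFactors = FALSE),
  prior_studies = c(kosmyna = 52, neuper = 56, koizumi = 84.6,
                    sousa = 87.64)
)
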