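# Bundled wild-type reference comparison data used to demonstrate and
# exercise the validation statistics.

#' Wild-type reference validation data
#'
#' Three small reference tables from a wild-type C. elegans embryo
#' simulation-versus-observation comparison, bundled so the validation
#' statistics can be demonstrated and recomputed without external downloads:
#'
#' * `"counts"` -- cell counts sampled every 5 minutes from a simulated and
#'   an observed embryo (30 sampling points). Where neither series had data
#'   on the common grid, the paired `sim_time` / `obs_time` values differ
#'   (minimum-time-difference pairing, see [sample_counts()]).
#' * `"cycles"` -- birth, division and cycle times (seconds) of 12 founder
#'   cells, with birth- and division-time SDs of the observational data and
#'   the cycle SD propagated in quadrature (see [cycle_sd()]).
#' * `"positions"` -- the 3-D positions of the same 12 founder cells at the
#'   moment of their division, with per-axis deviations.
#'
#' The `deviation` columns are part of the reference record and are used
#' as-is by the aggregate statistics; note that in the `"positions"` table
#' one row's recorded per-axis deviation differs from the recomputed
#' `|sim - obs|` difference, and the reference per-axis aggregates are only
#' reproducible from the recorded deviations (see the methods vignette).
#'
#' @param which One of `"counts"`, `"cycles"`, `"positions"`.
#' @return A tibble.
#' @examples
#' rmse(wt_reference("counts")$deviation)
#' @export
wt_reference <- function(which = c("counts", "cycles", "positions")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("wt_reference_", which, ".tsv"),
                      package = "elegansim", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
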