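#' Published virtual-screen hit table for CYP3A4
#'
#' The 115 food-derived compounds called as predicted CYP3A4 inhibitors by a
#' published fingerprint-based virtual screen of the FooDB food-compound
#' library, with the descriptor values (MW, AlogP, HBA, HBD) and prediction
#' indices reported there, plus literature IC50 annotations where the
#' compound's inhibitory potency had been characterised. `lit_call` records
#' the published classification of each annotated compound as a confirmed
#' (IC50 at or below 20 uM) or refuted inhibitor; unannotated compounds are
#' `"new"`. These are reported values, shipped as a worked-example input for
#' the intestinal-permeability filter and the literature-consistency check
#' -- they are not computed by this package.
#'
#' @return A tibble with 115 rows and columns `foodb_id`, `cas_no`, `name`,
#'   `mw`, `alogp`, `hba`, `hbd`, `pred_index`, `lit_ic50` (character, may
#'   carry `<`/`>` qualifiers), `lit_call`.
#' @examples
#' hits <- predicted_hits()
#' nrow(lro5_violations(hits, logp = alogp) |> intestinal_filter())
#' @export
predicted_hits <- function() {
  path <- system.file("extdata", "cyp3a4_predicted_hits.csv",
                      package = "cypscreen", mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE, check.names = TRUE))
}
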