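#' Packaged angiogenesis support-matrix fixture
#'
#' The t-invariant support matrix of a published qualitative Petri net model
#' of the molecular regulation of angiogenesis (HIF-1/VEGF/eNOS/TGF-beta
#' signaling; 63 places, 74 transitions, 48 minimal t-invariants). The matrix
#' is reconstructed from the model's printed invariant table: each invariant
#' is listed as a union of non-trivial MCT sets and single transitions, and
#' the MCT-set memberships expand those to the full 48 x 74 binary matrix.
#' The expected structural knockout ranking (26 knockout units with their
#' percentage of affected invariants) ships alongside.
#'
#' @return list with
#'   \describe{
#'     \item{support}{48 x 74 binary integer matrix, rows `x1..x48`, columns
#'       `t0..t73`}
#'     \item{mct_sets}{named list of the 11 published non-trivial MCT sets
#'       (`m1`..`m11`)}
#'     \item{knockout_expected}{data frame `unit`, `affected_percent`: the
#'       published structural knockout ranking}
#'   }
#' @examples
#' fx <- load_angiogenesis_fixture()
#' dim(fx$support)
#' @export
load_angiogenesis_fixture <- function() {
  path <- function(f) system.file("extdata", f, package = "petrinv", mustWork = TRUE)

  mct_df <- utils::read.csv(path("angio_mct_sets.csv"), stringsAsFactors = FALSE)
  mct_sets <- stats::setNames(strsplit(mct_df$transitions, " ", fixed = TRUE),
                              mct_df$set)

  comp <- utils::read.csv(path("angio_tinv_composition.csv"),
                          stringsAsFactors = FALSE)
  transitions <- paste0("t", 0:73)
  S <- matrix(0L, nrow(comp), length(transitions),
              dimnames = list(comp$invariant, transitions))
  split_ids <- function(s) if (is.na(s) || s == "") character() else strsplit(s, " ", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(comp))) {
    sets <- split_ids(comp$mct_sets[i])
    singles <- split_ids(comp$single_transitions[i])
    members <- c(unlist(mct_sets[sets], use.names = FALSE), singles)
    S[i, members] <- 1L
  }

  ko <- utils::read.csv(path("angio_knockout_expected.csv"),
                        stringsAsFactors = FALSE)
  list(support = S, mct_sets = mct_sets, knockout_expected = ko)
}
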