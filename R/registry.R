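#' @keywords internal
"_PACKAGE"

## Anatomical registry: the three apical views, their six segments and the
## two opposing walls ("sides") of each view. Segment labels: first letter
## B/M/A = basal/mid/apical level; the rest names the wall (S septal,
## L lateral, I inferior, A anterior, P posterior, As anteroseptal).

.VIEWS <- c("4ch", "3ch", "2ch")

.SEGMENTS <- list(
  "4ch" = c("BS", "MS", "AS", "BL", "ML", "AL"),
  "3ch" = c("BP", "MP", "AP", "BAs", "MAs", "AAs"),
  "2ch" = c("BI", "MI", "AI", "BA", "MA", "AA")
)

## sides listed in (sd1, sd2) order; side differences are sd1 - sd2
.SIDES <- list(
  "4ch" = list(S  = c("BS", "MS", "AS"),   L = c("BL", "ML", "AL")),
  "3ch" = list(As = c("BAs", "MAs", "AAs"), P = c("BP", "MP", "AP")),
  "2ch" = list(I  = c("BI", "MI", "AI"),   A = c("BA", "MA", "AA"))
)

#' Views supported by the feature scheme
#'
#' @return Character vector `c("4ch", "3ch", "2ch")`.
#' @export
strain_views <- function() .VIEWS

#' Segment labels of one apical view
#'
#' @param view One of `"4ch"`, `"3ch"`, `"2ch"`.
#' @return Character vector of the six segment labels of that view.
#' @export
view_segments <- function(view) {
  view <- match.arg(view, .VIEWS)
  .SEGMENTS[[view]]
}

#' Side (wall) membership of one apical view
#'
#' Each view opposes two walls of three segments each; side differences are
#' always first-listed minus second-listed (septal-lateral, anteroseptal-
#' posterior, inferior-anterior).
#'
#' @param view One of `"4ch"`, `"3ch"`, `"2ch"`.
#' @return Named list of two character vectors (segments per side).
#' @export
view_sides <- function(view) {
  view <- match.arg(view, .VIEWS)
  .SIDES[[view]]
}

## Feature-name grammar: <family>_<view>[_<qualifier>]
##   Tavc_4ch
##   P_4ch_BS ... P_4ch_mean  P_4ch_std          (8)
##   Tpeak_4ch_BS ... _mean _std                 (8)
##   dP_4ch   dTpeak_4ch                         (1 + 1)
##   Iavc_4ch_BS..  _mean _std _S _L _SmL        (11)
##   Ipeak_4ch_...  E_4ch_...                    (11 + 11)
## plus QRS and LVEF. 52 per view, 158 in total.
.integral_qualifiers <- function(view) {
  sides <- names(.SIDES[[view]])
  c(.SEGMENTS[[view]], "mean", "std", sides[1], sides[2],
    paste0(sides[1], "m", sides[2]))
}

.view_feature_names <- function(view) {
  segs <- .SEGMENTS[[view]]
  iq <- .integral_qualifiers(view)
  c(paste0("Tavc_", view),
    paste0("P_", view, "_", c(segs, "mean", "std")),
    paste0("Tpeak_", view, "_", c(segs, "mean", "std")),
    paste0("dP_", view),
    paste0("dTpeak_", view),
    paste0("Iavc_", view, "_", iq),
    paste0("Ipeak_", view, "_", iq),
    paste0("E_", view, "_", iq))
}

#' Canonical feature-name registry
#'
#' The 158 feature names in canonical order: per view (4ch, then 3ch, then
#' 2ch) the AVC time, peak magnitudes, peak timings, their heterogeneity and
#' dyssynchrony deltas, and the three strain-integral families (six segments,
#' mean, standard deviation, the two side sums and the side difference),
#' followed by the two clinician-supplied scalars QRS duration and LVEF.
#'
#' @return Character vector of length 158.
#' @export
feature_names <- function() {
  c(unlist(lapply(.VIEWS, .view_feature_names), use.names = FALSE),
    "QRS", "LVEF")
}

#' View of origin of a feature name
#'
#' @param names Character vector of feature names from [feature_names()].
#' @return Character vector: `"4ch"`, `"3ch"`, `"2ch"`, or `"none"` for the
#'   viewless clinical scalars (QRS, LVEF).
#' @export
feature_view <- function(names) {
  out <- rep("none", length(names))
  for (v in .VIEWS) out[grepl(paste0("(^|_)", v, "(_|$)"), names)] <- v
  out
}
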