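#' @title Core S4 classes
#' @name DamageClust-classes
#' @description S4 containers for event clouds, linkage analyses,
#'   classification schemes and yield reports.
NULL

#' EventSet: a cloud of inelastic track-structure events
#'
#' An `EventSet` holds one or more electron tracks as a table of inelastic
#' interaction events (ionizations and electronic excitations) with 3-D
#' coordinates in nm and per-event deposited energy in eV.  The derived
#' totals `nEvents` (event count, N_event) and `eDepKeV` (total deposited
#' energy in keV, E_dep) are stored and checked for consistency.
#'
#' @slot events `data.frame` with columns `track_id` (integer), `x_nm`,
#'   `y_nm`, `z_nm` (numeric, finite), `kind` (character, `"ION"` or
#'   `"EXC"`), `edep_eV` (numeric, strictly positive).
#' @slot nEvent integer, number of rows of `events`.
#' @slot eDepKeV numeric, sum of `edep_eV` / 1000.
#' @export
setClass("EventSet",
  representation(events = "data.frame", nEvent = "integer",
                 eDepKeV = "numeric"))

setValidity("EventSet", function(object) {
  ev <- object@events
  need <- c("track_id", "x_nm", "y_nm", "z_nm", "kind", "edep_eV")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns:", paste(need, collapse = ", ")))
  msgs <- character()
  if (object@nEvent != nrow(ev))
    msgs <- c(msgs, "nEvent does not equal nrow(events)")
  tot <- sum(ev$edep_eV) / 1000
  tol <- 1e-9 * max(1, abs(tot))
  if (abs(object@eDepKeV - tot) > tol)
    msgs <- c(msgs, "eDepKeV does not equal sum(edep_eV)/1000")
  if (nrow(ev) > 0) {
    if (!all(is.finite(ev$x_nm)) || !all(is.finite(ev$y_nm)) ||
        !all(is.finite(ev$z_nm)))
      msgs <- c(msgs, "coordinates must be finite")
    if (!all(ev$edep_eV > 0))
      msgs <- c(msgs, "edep_eV must be strictly positive")
    if (!all(ev$kind %in% c("ION", "EXC")))
      msgs <- c(msgs, "kind must be 'ION' or 'EXC'")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an EventSet from an event table
#'
#' @param events `data.frame` with columns `track_id`, `x_nm`, `y_nm`,
#'   `z_nm`, `kind` (`"ION"`/`"EXC"`), `edep_eV`.  May have zero rows.
#' @return A validated [EventSet-class] object with `nEvents` and
#'   `eDepKeV` populated.
#' @examples
#' es <- EventSet(data.frame(track_id = 1L, x_nm = 0, y_nm = 0, z_nm = 0,
#'                           kind = "ION", edep_eV = 1000))
#' eDepKeV(es)  # 1
#' @export
EventSet <- function(events = data.frame(track_id = integer(),
                                         x_nm = numeric(), y_nm = numeric(),
                                         z_nm = numeric(), kind = character(),
                                         edep_eV = numeric())) {
  events <- as.data.frame(events)
  events$track_id <- as.integer(events$track_id)
  events$kind <- as.character(events$kind)
  for (cc in c("x_nm", "y_nm", "z_nm", "edep_eV"))
    events[[cc]] <- as.numeric(events[[cc]])
  rownames(events) <- NULL
  new("EventSet", events = events, nEvent = nrow(events),
      eDepKeV = sum(events$edep_eV) / 1000)
}

#' TrackParams: parameters of the synthetic track generator
#'
#' Describes an isotropic random-walk electron track: exponentially
#' distributed step lengths between successive inelastic events and a
#' truncated-normal per-event energy deposit.
#'
#' @slot nEvents integer, number of events to generate (>= 0).
#' @slot meanFreePathNm numeric, mean step length in nm (> 0).
#' @slot edepMeanEv numeric, mean per-event deposit in eV (>= 1).
#' @slot edepSdEv numeric, standard deviation of the deposit in eV (>= 0).
#' @slot seed integer RNG seed.
#' @export
setClass("TrackParams",
  representation(nEvents = "integer", meanFreePathNm = "numeric",
                 edepMeanEv = "numeric", edepSdEv = "numeric",
                 seed = "integer"))

setValidity("TrackParams", function(object) {
  msgs <- character()
  if (object@nEvents < 0) msgs <- c(msgs, "nEvents must be >= 0")
  if (!(object@meanFreePathNm > 0))
    msgs <- c(msgs, "meanFreePathNm must be > 0")
  if (object@edepMeanEv < 1) msgs <- c(msgs, "edepMeanEv must be >= 1")
  if (object@edepSdEv < 0) msgs <- c(msgs, "edepSdEv must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' LinkageResult: linkage sites found at a given L_c
#'
#' Produced by [countLinkages()].  Each site is one unordered pair of
#' events separated by at most `lcNm`, with its midpoint and the number of
#' events per cluster `n_cl` (events within `lcNm` of the midpoint,
#' including the pair itself).
#'
#' @slot nLink integer, total number of linkages (= `nrow(sites)`).
#' @slot sites `data.frame` with columns `i`, `j` (1-based event indices),
#'   `cx_nm`, `cy_nm`, `cz_nm` (site centre), `dist_nm` (pair separation),
#'   `n_cl` (integer, >= 2).
#' @slot lcBp numeric, the maximum inter-lesion distance used, in bp.
#' @slot lcNm numeric, the same distance in nm.
#' @slot pairing character, `"all"` or `"greedy"`.
#' @export
setClass("LinkageResult",
  representation(nLink = "integer", sites = "data.frame", lcBp = "numeric",
                 lcNm = "numeric", pairing = "character"))

setValidity("LinkageResult", function(object) {
  msgs <- character()
  if (object@nLink != nrow(object@sites))
    msgs <- c(msgs, "nLink does not equal nrow(sites)")
  if (object@nLink > 0 && any(object@sites$n_cl < 2))
    msgs <- c(msgs, "every site must have n_cl >= 2")
  if (object@nLink > 0 && any(object@sites$dist_nm > object@lcNm))
    msgs <- c(msgs, "site pair separation exceeds lcNm")
  if (length(msgs)) msgs else TRUE
})

#' ClassificationScheme: N_cl bins mapping sites to damage types
#'
#' Ordered, contiguous half-open integer bins `[lower, upper)` on the
#' events-per-cluster count N_cl.  Each bin carries two labels, one for the
#' double-strand-break stream and one for the clustered-base-damage stream
#' (the latter is `NA` in the strand-break scheme), plus the number of base
#' damages each label implies (used for per-lesion detection thinning).
#'
#' @slot name character, `"BD_SCHEME"` or `"SB_SCHEME"`.
#' @slot lower,upper integer vectors of bin edges, contiguous.
#' @slot dsbLabels character labels for DSB-site classification.
#' @slot bdLabels character labels for cBD-site classification.
#' @slot dsbBDCount,bdBDCount integer, base damages per label.
#' @seealso [bdScheme()], [sbScheme()]
#' @export
setClass("ClassificationScheme",
  representation(name = "character", lower = "integer", upper = "integer",
                 dsbLabels = "character", bdLabels = "character",
                 dsbBDCount = "integer", bdBDCount = "integer"))

setValidity("ClassificationScheme", function(object) {
  k <- length(object@lower)
  if (length(object@upper) != k || length(object@dsbLabels) != k)
    return("bin edge and label vectors must have equal length")
  msgs <- character()
  if (any(object@upper <= object@lower))
    msgs <- c(msgs, "each bin must have upper > lower")
  if (k > 1 && any(object@lower[-1] != object@upper[-k]))
    msgs <- c(msgs, "bins must be contiguous and non-overlapping")
  if (length(msgs)) msgs else TRUE
})

#' ClassFractions: per-bin site fractions f(N_cl)
#'
#' Produced by [classFractions()].  Fractions are computed per site; sites
#' with N_cl at or above the top bin edge are tallied separately in the
#' overflow bucket so that `sum(fraction) + overflowFraction == 1` whenever
#' sites exist.
#'
#' @slot scheme character, name of the scheme used.
#' @slot bins `data.frame` with columns `lower`, `upper`, `dsbLabel`,
#'   `bdLabel`, `nSites`, `fraction`.
#' @slot overflowN integer, sites with N_cl above the top edge.
#' @slot overflowFraction numeric share of such sites.
#' @slot nLink integer, total sites classified.
#' @slot empty logical, `TRUE` when there were no sites at all.
#' @export
setClass("ClassFractions",
  representation(scheme = "character", bins = "data.frame",
                 overflowN = "integer", overflowFraction = "numeric",
                 nLink = "integer", empty = "logical"))

setValidity("ClassFractions", function(object) {
  msgs <- character()
  fr <- c(object@bins$fraction, object@overflowFraction)
  if (any(fr < 0) || any(fr > 1))
    msgs <- c(msgs, "fractions must lie in [0, 1]")
  if (!object@empty && abs(sum(fr) - 1) > 1e-12)
    msgs <- c(msgs, "fractions plus overflow must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' YieldReport: damage yields, fractions and derived ratios
#'
#' The end product of the analysis pipeline ([runAnalysis()]).  Yields are
#' in Gy^-1 Da^-1.  When a detection model is applied the corrected values
#' live under `detection$corrected`; the uncorrected slots are untouched.
#'
#' @slot params list of analysis parameters (L_c values in bp, bp-to-nm
#'   factor, scheme name, pairing convention, coefficients, seed if any).
#' @slot counts list with `nEvent`, `eDepKeV` and `nLink` (named by L_c).
#' @slot yields list with `ySSB`, `yDSB`, `yBD`, `yCBD`, per-label splits
#'   `perLabel`, and `yCBDStar` when the detection-loss correction is on.
#' @slot fractions `data.frame` of per-label site fractions.
#' @slot ratios list with `bd_ssb`, `cbd_bd`, `dsb_ssb`, `cdsb_dsb`.
#' @slot detection list with `eta`, `arpLoss`, `mode`, `corrected` (empty
#'   list when no detection model was applied).
#' @slot empty logical, `TRUE` for an event set with no events.
#' @export
setClass("YieldReport",
  representation(params = "list", counts = "list", yields = "list",
                 fractions = "data.frame", ratios = "list",
                 detection = "list", empty = "logical"))
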