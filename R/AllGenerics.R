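#' Accessors for DamageClust classes
#'
#' @param x an object.
#' @return `events()` the event `data.frame`; `nEvents()` the event count
#'   N_event; `eDepKeV()` the total deposited energy E_dep in keV;
#'   `nLink()` the linkage count N_link; `sites()` the site `data.frame`;
#'   `fractions()` the per-bin fraction table; `overflowFraction()` the
#'   share of sites above the top classification bin; `yields()` the list
#'   of damage yields in Gy^-1 Da^-1.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))
#' @rdname accessors
#' @export
setGeneric("eDepKeV", function(x) standardGeneric("eDepKeV"))
#' @rdname accessors
#' @export
setGeneric("nLink", function(x) standardGeneric("nLink"))
#' @rdname accessors
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))
#' @rdname accessors
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))
#' @rdname accessors
#' @export
setGeneric("overflowFraction", function(x) standardGeneric("overflowFraction"))
#' @rdname accessors
#' @export
setGeneric("yields", function(x) standardGeneric("yields"))

#' @rdname accessors
setMethod("events", "EventSet", function(x) x@events)
#' @rdname accessors
setMethod("nEvents", "EventSet", function(x) x@nEvent)
#' @rdname accessors
setMethod("eDepKeV", "EventSet", function(x) x@eDepKeV)
#' @rdname accessors
setMethod("nLink", "LinkageResult", function(x) x@nLink)
#' @rdname accessors
setMethod("sites", "LinkageResult", function(x) x@sites)
#' @rdname accessors
setMethod("fractions", "ClassFractions", function(x) x@bins)
#' @rdname accessors
setMethod("overflowFraction", "ClassFractions", function(x) x@overflowFraction)
#' @rdname accessors
setMethod("fractions", "YieldReport", function(x) x@fractions)
#' @rdname accessors
setMethod("yields", "YieldReport", function(x) x@yields)

setMethod("show", "EventSet", function(object) {
  cat(sprintf("EventSet with %d events, E_dep = %.6g keV\n",
              object@nEvent, object@eDepKeV))
  if (object@nEvent > 0) {
    cat(sprintf("  tracks: %d | ionizations: %d | excitations: %d\n",
                length(unique(object@events$track_id)),
                sum(object@events$kind == "ION"),
                sum(object@events$kind == "EXC")))
    print(head(object@events, 5))
    if (object@nEvent > 5) cat(sprintf("  ... and %d more\n", object@nEvent - 5))
  }
  invisible(NULL)
})

setMethod("show", "LinkageResult", function(object) {
  cat(sprintf("LinkageResult: N_link = %d at L_c = %g bp (%.4g nm), %s pairing\n",
              object@nLink, object@lcBp, object@lcNm, object@pairing))
  if (object@nLink > 0)
    cat(sprintf("  N_cl range: %d-%d (mean %.2f)\n", min(object@sites$n_cl),
                max(object@sites$n_cl), mean(object@sites$n_cl)))
  invisible(NULL)
})

setMethod("show", "ClassificationScheme", function(object) {
  cat(sprintf("ClassificationScheme '%s'\n", object@name))
  for (k in seq_along(object@lower)) {
    lab <- object@dsbLabels[k]
    if (!is.na(object@bdLabels[k])) lab <- paste(lab, object@bdLabels[k], sep = " | ")
    cat(sprintf("  %2d <= N_cl < %2d : %s\n", object@lower[k], object@upper[k], lab))
  }
  invisible(NULL)
})

setMethod("show", "ClassFractions", function(object) {
  cat(sprintf("ClassFractions (%s) over %d sites%s\n", object@scheme,
              object@nLink, if (object@empty) " [empty]" else ""))
  print(object@bins[, c("lower", "upper", "dsbLabel", "bdLabel", "nSites",
                        "fraction")])
  if (object@overflowN > 0)
    cat(sprintf("  overflow: %d sites (%.4f)\n", object@overflowN,
                object@overflowFraction))
  invisible(NULL)
})

setMethod("show", "YieldReport", function(object) {
  cat("YieldReport", if (object@empty) "[empty event set]", "\n")
  cat(sprintf("  N_event = %d, E_dep = %.6g keV\n",
              object@counts$nEvent, object@counts$eDepKeV))
  nl <- object@counts$nLink
  cat("  N_link:", paste(sprintf("%s = %d", names(nl), unlist(nl)),
                         collapse = ", "), "\n")
  y <- object@yields
  cat(sprintf("  Y_SSB = %.4g  Y_DSB = %.4g  Y_BD = %.4g  Y_cBD = %.4g  (Gy^-1 Da^-1)\n",
              y$ySSB, y$yDSB, y$yBD, y$yCBD))
  if (!is.null(y$yCBDStar))
    cat(sprintf("  Y*_cBD (detection loss) = %.4g\n", y$yCBDStar))
  if (length(object@detection) && !is.null(object@detection$eta))
    cat(sprintf("  detection: eta = %g (%s mode)\n", object@detection$eta,
                object@detection$mode))
  invisible(NULL)
})
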