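# Linkage counting, N_cl computation and site classification.
#
# A linkage is an unordered pair of inelastic events whose Euclidean
# separation is at most L_c (expressed in bp, converted at 0.34 nm/bp).
# Distance boundaries are closed (<= L_c).  By default ALL qualifying pairs
# count as linkages, so a single event may participate in several sites; a
# greedy unique-pairing mode (nearest pairs first, each event used at most
# once) is available for sensitivity analysis.  Each site's events-per-
# cluster count N_cl is the number of events within L_c of the pair
# midpoint, the linked pair included, hence N_cl >= 2.

eventCoords <- function(es) {
  as.matrix(es@events[, c("x_nm", "y_nm", "z_nm"), drop = FALSE])
}

# greedy unique pairing: shortest pairs first, deterministic (i, j) tie-break
greedyPairs <- function(pairs, d) {
  ord <- order(d, pairs[, 1], pairs[, 2])
  used <- logical(max(pairs, 0))
  keep <- logical(nrow(pairs))
  for (k in ord) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!used[i] && !used[j]) {
      keep[k] <- TRUE
      used[i] <- TRUE
      used[j] <- TRUE
    }
  }
  keep
}

#' Count linkages within L_c and build sites
#'
#' Finds every unordered pair of events with separation at most
#' `lcBp * bpToNm` nanometres (closed boundary) via a uniform-grid spatial
#' index, builds one site per linkage at the pair midpoint and computes its
#' events-per-cluster count N_cl.  The result is independent of the event
#' ordering and of rigid-body transforms of the coordinates.
#'
#' @param es an [EventSet-class].
#' @param lcBp maximum inter-lesion distance L_c in base pairs (default 10
#'   bp = 3.4 nm, the classical distance for two strand breaks to form a
#'   double-strand break).
#' @param bpToNm base-pair length in nm (default [BP_TO_NM]).
#' @param pairing `"all"` (every qualifying pair is a linkage, the
#'   default) or `"greedy"` (unique pairing, nearest pairs first).
#' @return A [LinkageResult-class].
#' @examples
#' es <- EventSet(data.frame(track_id = 1L, x_nm = c(0, 3), y_nm = 0,
#'                           z_nm = 0, kind = "ION", edep_eV = 20))
#' nLink(countLinkages(es, lcBp = 10))  # 1
#' @export
countLinkages <- function(es, lcBp = 10, bpToNm = BP_TO_NM,
                          pairing = c("all", "greedy")) {
  stopifnot(is(es, "EventSet"), lcBp > 0, bpToNm > 0)
  pairing <- match.arg(pairing)
  lcNm <- lcBp * bpToNm
  pts <- eventCoords(es)
  pairs <- .cpp_pairs_within(pts, lcNm)
  if (nrow(pairs) > 0) {
    d <- sqrt(rowSums((pts[pairs[, 1], , drop = FALSE] -
                       pts[pairs[, 2], , drop = FALSE])^2))
    if (pairing == "greedy") {
      keep <- greedyPairs(pairs, d)
      pairs <- pairs[keep, , drop = FALSE]
      d <- d[keep]
    }
  } else {
    d <- numeric()
  }
  ctr <- (pts[pairs[, 1], , drop = FALSE] +
          pts[pairs[, 2], , drop = FALSE]) / 2
  ncl <- as.integer(.cpp_radius_counts(pts, ctr, lcNm))
  st <- data.frame(i = pairs[, 1], j = pairs[, 2],
                   cx_nm = ctr[, 1], cy_nm = ctr[, 2], cz_nm = ctr[, 3],
                   dist_nm = d, n_cl = ncl)
  rownames(st) <- NULL
  new("LinkageResult", nLink = nrow(st), sites = st, lcBp = lcBp,
      lcNm = lcNm, pairing = pairing)
}

#' Events per cluster at given sites
#'
#' Counts, for each site centre, the events of `es` within the L_c radius
#' (closed boundary), the linked pair included.
#'
#' @param siteTab site `data.frame` as in [LinkageResult-class] (columns
#'   `cx_nm`, `cy_nm`, `cz_nm`), or a [LinkageResult-class].
#' @inheritParams countLinkages
#' @return Integer vector of N_cl values.
#' @export
computeNcl <- function(siteTab, es, lcBp = 10, bpToNm = BP_TO_NM) {
  if (is(siteTab, "LinkageResult")) siteTab <- siteTab@sites
  stopifnot(is(es, "EventSet"))
  ctr <- as.matrix(siteTab[, c("cx_nm", "cy_nm", "cz_nm"), drop = FALSE])
  as.integer(.cpp_radius_counts(eventCoords(es), ctr, lcBp * bpToNm))
}

# --- classification schemes ------------------------------------------------

#' Events-per-lesion constants
#'
#' On average 9 ionization/excitation events per cluster are needed to
#' induce one additional base damage at a double-strand-break or clustered-
#' base-damage site.  Combined with the base-damage to strand-break
#' induction ratio of 1.3, one additional strand break requires
#' 9 x 1.3 = 11.7, i.e. 12 events on average after rounding.
#'
#' @return Number of events per additional lesion.
#' @export
eventsPerAdditionalBD <- function() 9

#' @rdname eventsPerAdditionalBD
#' @param eventsPerBD events per additional base damage.
#' @param bdSsbRatio base-damage to strand-break induction ratio.
#' @export
eventsPerAdditionalSB <- function(eventsPerBD = eventsPerAdditionalBD(),
                                  bdSsbRatio = 1.3) {
  eventsPerBD * bdSsbRatio
}

#' Classification schemes for complex-damage sites
#'
#' `bdScheme()` classifies sites by the number of base damages they carry:
#' N_cl bins `[2, 11)`, `[11, 20)`, `[20, 29)` map double-strand-break
#' sites to DSB, DSB/BD, DSB/BD/BD and clustered-base-damage sites to
#' BD/BD, BD/BD/BD, BD/BD/BD/BD (bin width = 9 events per additional base
#' damage).  `sbScheme()` classifies double-strand-break sites by
#' additional strand breaks: bins `[2, 14)`, `[14, 26)`, `[26, 38)` map to
#' DSB, DSB+, DSB++ (bin width = 12 events per additional strand break).
#'
#' @return A [ClassificationScheme-class].
#' @export
bdScheme <- function() {
  w <- eventsPerAdditionalBD()
  lo <- as.integer(2 + w * (0:2))
  new("ClassificationScheme", name = "BD_SCHEME", lower = lo,
      upper = as.integer(lo + w),
      dsbLabels = c("DSB", "DSB/BD", "DSB/BD/BD"),
      bdLabels = c("BD/BD", "BD/BD/BD", "BD/BD/BD/BD"),
      dsbBDCount = 0:2, bdBDCount = 2:4)
}

#' @rdname bdScheme
#' @export
sbScheme <- function() {
  w <- as.integer(round(eventsPerAdditionalSB()))
  lo <- as.integer(2 + w * (0:2))
  new("ClassificationScheme", name = "SB_SCHEME", lower = lo,
      upper = as.integer(lo + w),
      dsbLabels = c("DSB", "DSB+", "DSB++"),
      bdLabels = rep(NA_character_, 3), dsbBDCount = c(0L, 0L, 0L),
      bdBDCount = c(NA_integer_, NA_integer_, NA_integer_))
}

getScheme <- function(scheme) {
  if (is(scheme, "ClassificationScheme")) return(scheme)
  switch(match.arg(toupper(scheme), c("BD_SCHEME", "SB_SCHEME", "BD", "SB")),
         BD_SCHEME = , BD = bdScheme(),
         SB_SCHEME = , SB = sbScheme())
}

#' Classify sites by events per cluster
#'
#' Maps N_cl values to damage-type labels through a scheme's half-open
#' integer bins.  Values at or above the top bin edge are clamped to the
#' most complex label and flagged as overflow (attribute `"overflow"`, a
#' logical vector).
#'
#' @param nCl integer vector of events-per-cluster counts (all >= 2).
#' @param scheme a [ClassificationScheme-class], or `"BD"` / `"SB"`.
#' @param stream `"dsb"` to label sites as double-strand-break types,
#'   `"bd"` to label them as clustered-base-damage types.
#' @return Character vector of labels with attribute `overflow`.
#' @examples
#' classifySite(c(6, 15, 24), bdScheme())        # DSB, DSB/BD, DSB/BD/BD
#' classifySite(c(6, 15, 27), sbScheme())        # DSB, DSB+, DSB++
#' @export
classifySite <- function(nCl, scheme = bdScheme(), stream = c("dsb", "bd")) {
  scheme <- getScheme(scheme)
  stream <- match.arg(stream)
  if (any(nCl < 2))
    stop("n_cl < 2: not a complex-damage site (isolated events are not classified)")
  labs <- if (stream == "dsb") scheme@dsbLabels else scheme@bdLabels
  k <- length(scheme@lower)
  idx <- findInterval(nCl, c(scheme@lower, scheme@upper[k]))
  over <- idx > k
  idx[over] <- k  # clamp to the most complex label
  out <- labs[idx]
  attr(out, "overflow") <- over
  out
}

#' Per-bin site fractions f(N_cl)
#'
#' Tallies the sites of a [LinkageResult-class] into the scheme's bins and
#' normalizes per site.  Sites with N_cl at or above the top edge go to
#' the overflow bucket, so bin fractions plus the overflow fraction sum to
#' one whenever sites exist.  With no sites all fractions are zero and the
#' result is flagged empty.
#'
#' @param lr a [LinkageResult-class].
#' @param scheme a [ClassificationScheme-class], or `"BD"` / `"SB"`.
#' @return A [ClassFractions-class].
#' @export
classFractions <- function(lr, scheme = bdScheme()) {
  stopifnot(is(lr, "LinkageResult"))
  scheme <- getScheme(scheme)
  k <- length(scheme@lower)
  nSites <- integer(k)
  overN <- 0L
  if (lr@nLink > 0) {
    idx <- findInterval(lr@sites$n_cl, c(scheme@lower, scheme@upper[k]))
    overN <- sum(idx > k)
    nSites <- tabulate(idx[idx <= k], nbins = k)
  }
  tot <- lr@nLink
  frac <- if (tot > 0) nSites / tot else numeric(k)
  bins <- data.frame(lower = scheme@lower, upper = scheme@upper,
                     dsbLabel = scheme@dsbLabels, bdLabel = scheme@bdLabels,
                     nSites = nSites, fraction = frac,
                     stringsAsFactors = FALSE)
  new("ClassFractions", scheme = scheme@name, bins = bins,
      overflowN = as.integer(overN),
      overflowFraction = if (tot > 0) overN / tot else 0,
      nLink = lr@nLink, empty = tot == 0)
}
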