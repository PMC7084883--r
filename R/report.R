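# Pipeline orchestration and report generation.

#' Complex-DSB share of the double-strand-break yield
#'
#' The complex share cDSB/DSB is the percentage of double-strand-break
#' yield carried by DSB sites coupled with additional strand breaks:
#' `100 * (DSB+ + DSB++) / (DSB + DSB+ + DSB++)`.  Inputs may be
#' percentages, fractions or absolute yields; only their ratio matters.
#'
#' @param fractions named numeric containing `DSB`, `DSB+` and `DSB++`.
#' @return The complex-DSB percentage.
#' @examples
#' cdsbRatio(c(DSB = 10.13, `DSB+` = 2.57, `DSB++` = 0.00))  # 20.24
#' @export
cdsbRatio <- function(fractions) {
  need <- c("DSB", "DSB+", "DSB++")
  if (!all(need %in% names(fractions)))
    stop("fractions must contain entries named: ", paste(need, collapse = ", "))
  simple <- as.numeric(fractions["DSB"])
  complex <- as.numeric(fractions["DSB+"]) + as.numeric(fractions["DSB++"])
  if (simple + complex <= 0)
    stop("undefined ratio: DSB + DSB+ + DSB++ is zero")
  100 * complex / (simple + complex)
}

#' Run the full damage-yield analysis
#'
#' Orchestrates the pipeline: read (or synthesize) an event cloud, count
#' linkages at each requested L_c, classify the sites at the primary L_c
#' (the first of `lcBp`), compute the yields of Eqs for strand breaks and
#' base damage, split them over the classification bins, derive the yield
#' ratios, and optionally apply the detection-efficiency and
#' detection-loss corrections.  Given the same input file, or the same
#' generator parameters and seed, the result is fully deterministic.
#'
#' @param input path to a TSV event table, or `NULL` to synthesize.
#' @param params a [TrackParams-class] for the synthetic generator
#'   (exactly one of `input` / `params` must be given).
#' @param lcBp numeric vector of linkage distances in bp; the first is the
#'   primary analysis distance.  Must contain 10 (the double-strand-break
#'   definition); 5 is added automatically when `arpLoss = TRUE`.
#' @param scheme `"BD"`, `"SB"` or a [ClassificationScheme-class].
#' @param coef coefficients from [damageCoefficients()].
#' @param eta optional per-base-damage detection efficiency in `[0, 1]`.
#' @param etaMode `"per-lesion"` or `"strict"`, see [applyDetection()].
#' @param arpLoss apply the probe-size detection loss
#'   `Y*_cBD = Y_cBD(10 bp) - Y_cBD(5 bp)`?
#' @param pairing linkage pairing convention, see [countLinkages()].
#' @param bpToNm base-pair length in nm.
#' @param output optional path; when given the report is written there as
#'   JSON via [writeYieldReport()].
#' @return A [YieldReport-class].
#' @examples
#' rep <- runAnalysis(params = trackParams(nEvents = 300, seed = 11))
#' yields(rep)$ySSB
#' @export
runAnalysis <- function(input = NULL, params = NULL, lcBp = c(10, 5),
                        scheme = "BD", coef = damageCoefficients(),
                        eta = NULL, etaMode = "per-lesion", arpLoss = FALSE,
                        pairing = "all", bpToNm = BP_TO_NM, output = NULL) {
  if (is.null(input) == is.null(params))
    stop("exactly one of 'input' (event table) or 'params' (synthetic ",
         "track parameters) must be given")
  if (arpLoss && !(5 %in% lcBp)) lcBp <- c(lcBp, 5)
  if (!(10 %in% lcBp))
    stop("lcBp must include 10 bp, the double-strand-break distance")
  sch <- getScheme(scheme)
  es <- if (!is.null(input)) readEvents(input) else generateTrack(params)

  lrs <- lapply(lcBp, function(lc)
    countLinkages(es, lcBp = lc, bpToNm = bpToNm, pairing = pairing))
  names(lrs) <- paste0(lcBp, "bp")
  primary <- lrs[[1]]
  lr10 <- lrs[[which(lcBp == 10)[1]]]
  cf <- classFractions(primary, sch)

  empty <- es@nEvent == 0
  if (empty) {
    ySSB <- yDSB <- yBD <- 0
    yCBD <- structure(0, lcBp = primary@lcBp)
  } else {
    ySSB <- yieldSSB(es, coef)
    yDSB <- yieldDSB(lr10, es, coef)
    yBD <- yieldBD(es, coef)
    yCBD <- yieldCBD(primary, es, coef)
  }
  perLabel <- list(dsb = splitByClass(yDSB, cf, "dsb"))
  if (!anyNA(cf@bins$bdLabel))
    perLabel$bd <- splitByClass(as.numeric(yCBD), cf, "bd")

  yl <- list(ySSB = ySSB, yDSB = yDSB, yBD = yBD,
             yCBD = as.numeric(yCBD), perLabel = perLabel)
  if (arpLoss) {
    lr5 <- lrs[[which(lcBp == 5)[1]]]
    yCbd5 <- if (empty) structure(0, lcBp = 5) else yieldCBD(lr5, es, coef)
    yl$yCBDStar <- detectionLoss(structure(as.numeric(yCBD), lcBp = 10),
                                 yCbd5)
  }

  dsbSplit <- perLabel$dsb
  simpleDsb <- dsbSplit[[1]]
  complexDsb <- sum(dsbSplit[-1])  # beyond the first bin, overflow included
  ratios <- list(
    bd_ssb = if (empty) NA_real_ else yBD / ySSB,
    cbd_bd = if (empty || yBD == 0) NA_real_ else as.numeric(yCBD) / yBD,
    dsb_ssb = if (empty || ySSB == 0) NA_real_ else yDSB / ySSB,
    cdsb_dsb = if (simpleDsb + complexDsb > 0)
      100 * complexDsb / (simpleDsb + complexDsb) else NA_real_)

  counts <- list(nEvent = es@nEvent, eDepKeV = es@eDepKeV,
                 nLink = lapply(lrs, nLink))
  prm <- list(lcBp = lcBp, bpToNm = bpToNm, scheme = sch@name,
              pairing = pairing, arpLoss = arpLoss, coefficients = coef)
  if (!is.null(params))
    prm$track <- list(nEvents = params@nEvents,
                      meanFreePathNm = params@meanFreePathNm,
                      edepMeanEv = params@edepMeanEv,
                      edepSdEv = params@edepSdEv, seed = params@seed)

  report <- new("YieldReport", params = prm, counts = counts, yields = yl,
                fractions = cf@bins, ratios = ratios,
                detection = list(), empty = empty)
  report@params$overflowFraction <- cf@overflowFraction
  if (!is.null(eta)) report <- applyDetection(report, eta, mode = etaMode)
  if (!is.null(output)) writeYieldReport(report, output)
  report
}

reportAsList <- function(report) {
  y <- report@yields
  yl <- list(ySSB = y$ySSB, yDSB = y$yDSB, yBD = y$yBD, yCBD = y$yCBD)
  if (!is.null(y$yCBDStar)) yl$yCBDStar <- y$yCBDStar
  yl$perLabel <- lapply(y$perLabel, as.list)
  det <- report@detection
  if (length(det) && !is.null(det$corrected))
    det$corrected$perLabel <- lapply(det$corrected$perLabel, as.list)
  list(params = report@params, counts = report@counts, yields = yl,
       fractions = report@fractions, ratios = report@ratios,
       detection = det, empty = report@empty)
}

#' Write / read a yield report as JSON
#'
#' The JSON is canonical and timestamp-free, so identical analyses produce
#' byte-identical files.
#'
#' @param report a [YieldReport-class].
#' @param path output (input) path.
#' @return `writeYieldReport()`: `path` invisibly; `readYieldReport()`:
#'   the report as a nested list.
#' @export
writeYieldReport <- function(report, path) {
  stopifnot(is(report, "YieldReport"))
  jsonlite::write_json(reportAsList(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname writeYieldReport
#' @export
readYieldReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Human-readable fraction table
#'
#' One row per damage-type label with the site count of its bin, its
#' fraction f(N_cl) and its yield share, for each label stream of the
#' report (plus the overflow component when present).
#'
#' @param report a [YieldReport-class].
#' @param corrected use detection-corrected yields when available?
#' @return `data.frame` with columns `label`, `n_sites`, `fraction`,
#'   `yield`.
#' @export
fractionTable <- function(report, corrected = FALSE) {
  stopifnot(is(report, "YieldReport"))
  per <- if (corrected && length(report@detection))
    report@detection$corrected$perLabel else report@yields$perLabel
  bins <- report@fractions
  over <- report@params$overflowFraction
  rows <- lapply(names(per), function(stream) {
    v <- per[[stream]]
    data.frame(label = names(v),
               n_sites = c(bins$nSites, NA_integer_),
               fraction = c(bins$fraction, over),
               yield = as.numeric(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[out$label != "overflow" | out$fraction > 0, , drop = FALSE]
}

#' Read a run configuration file
#'
#' YAML configuration mirroring the arguments of [runAnalysis()]: top-level
#' keys `input`, `track` (with `nEvents`, `meanFreePathNm`, `edepMeanEv`,
#' `edepSdEv`, `seed`), `lcBp`, `scheme`, `coefficients` (overrides for
#' [damageCoefficients()]), `eta`, `etaMode`, `arpLoss`, `pairing`,
#' `bpToNm`, `output`.
#'
#' @param path path to the YAML file.
#' @return Argument list suitable for `do.call(runAnalysis, ...)`.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$input)) args$input <- cfg$input
  if (!is.null(cfg$track)) args$params <- do.call(trackParams, cfg$track)
  for (key in c("lcBp", "scheme", "eta", "etaMode", "arpLoss", "pairing",
                "bpToNm", "output"))
    if (!is.null(cfg[[key]])) args[[key]] <- cfg[[key]]
  if (!is.null(cfg$lcBp)) args$lcBp <- as.numeric(unlist(cfg$lcBp))
  if (!is.null(cfg$coefficients))
    args$coef <- do.call(damageCoefficients, cfg$coefficients)
  args
}
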