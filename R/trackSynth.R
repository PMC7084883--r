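# Synthetic electron-track generator.
#
# A deliberately simple stochastic stand-in for a track-structure transport
# engine: inelastic events are laid down along an isotropic random walk with
# exponentially distributed step lengths, and each event deposits an energy
# drawn from a normal distribution truncated at the 1 eV transport cut-off.
# The walk has no cross-section physics; only the spatial density of events
# (set by the mean free path) and the deposited-energy sum matter downstream.

# Run code under a named, versioned RNG so fixtures are stable across
# releases, restoring the caller's RNG state afterwards.
withTrackRNG <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

rtruncEdep <- function(n, mean, sd) {
  if (n == 0) return(numeric())
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  while (any(low <- out < EDEP_CUTOFF_EV))
    out[low] <- rnorm(sum(low), mean, sd)
  out
}

runifSphere <- function(n) {
  # isotropic unit vectors
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Synthetic track parameters
#'
#' Constructs a validated [TrackParams-class].  Defaults describe a dense
#' sub-keV electron track: 1000 inelastic events with a 3 nm mean free path
#' and a 20 +/- 10 eV per-event deposit (truncated at the 1 eV cut-off).
#'
#' @param nEvents number of events (>= 0).
#' @param meanFreePathNm mean step length between events in nm (> 0).
#' @param edepMeanEv,edepSdEv mean and sd of the per-event deposit (eV).
#' @param seed RNG seed (integer).
#' @return A [TrackParams-class].
#' @export
trackParams <- function(nEvents = 1000, meanFreePathNm = 3,
                        edepMeanEv = 20, edepSdEv = 10, seed = 1) {
  new("TrackParams", nEvents = as.integer(nEvents),
      meanFreePathNm = as.numeric(meanFreePathNm),
      edepMeanEv = as.numeric(edepMeanEv), edepSdEv = as.numeric(edepSdEv),
      seed = as.integer(seed))
}

#' Generate a synthetic electron track
#'
#' Places exactly `p@nEvents` events along an isotropic random walk
#' starting at the origin, with step lengths drawn from an exponential
#' distribution with mean `p@meanFreePathNm`.  The same parameters and
#' seed always yield the identical [EventSet-class].
#'
#' @param p a [TrackParams-class].
#' @param trackId integer label stored in the `track_id` column.
#' @return An [EventSet-class].
#' @examples
#' es <- generateTrack(trackParams(nEvents = 100, seed = 7))
#' nEvents(es)  # 100
#' @export
generateTrack <- function(p, trackId = 1L) {
  stopifnot(is(p, "TrackParams"))
  validObject(p)
  n <- p@nEvents
  if (n == 0) return(EventSet())
  withTrackRNG(p@seed, {
    if (n == 1) {
      pos <- matrix(0, 1, 3)
    } else {
      steps <- rexp(n - 1, rate = 1 / p@meanFreePathNm)
      dirs <- runifSphere(n - 1)
      disp <- dirs * steps
      pos <- rbind(c(0, 0, 0),
                   cbind(cumsum(disp[, 1]), cumsum(disp[, 2]),
                         cumsum(disp[, 3])))
    }
    kind <- ifelse(runif(n) < 0.5, "ION", "EXC")
    edep <- rtruncEdep(n, p@edepMeanEv, p@edepSdEv)
    EventSet(data.frame(track_id = as.integer(trackId), x_nm = pos[, 1],
                        y_nm = pos[, 2], z_nm = pos[, 3], kind = kind,
                        edep_eV = edep, stringsAsFactors = FALSE))
  })
}

#' Generate a uniform spherical blob of events
#'
#' Test fixture with a known cluster structure: `n` events uniformly
#' distributed in a ball of radius `radiusNm` centred at the origin.  For
#' `radiusNm <= lcNm / 2` every pair of events is within the linkage
#' distance, so every site found at that L_c has exactly `n_cl = n`.
#'
#' @param n number of events (>= 0).
#' @param radiusNm ball radius in nm (> 0).
#' @param seed RNG seed.
#' @param edepMeanEv,edepSdEv per-event deposit distribution (eV).
#' @return An [EventSet-class].
#' @examples
#' blob <- generateBlob(6, radiusNm = 1, seed = 1)
#' lr <- countLinkages(blob, lcBp = 10)
#' unique(sites(lr)$n_cl)  # 6
#' @export
generateBlob <- function(n, radiusNm = 1, seed = 1, edepMeanEv = 20,
                         edepSdEv = 10) {
  stopifnot(n >= 0, radiusNm > 0)
  n <- as.integer(n)
  if (n == 0) return(EventSet())
  withTrackRNG(seed, {
    r <- radiusNm * runif(n)^(1 / 3)
    pos <- runifSphere(n) * r
    kind <- ifelse(runif(n) < 0.5, "ION", "EXC")
    edep <- rtruncEdep(n, edepMeanEv, edepSdEv)
    EventSet(data.frame(track_id = 1L, x_nm = pos[, 1], y_nm = pos[, 2],
                        z_nm = pos[, 3], kind = kind, edep_eV = edep,
                        stringsAsFactors = FALSE))
  })
}
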