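# Seeded synthetic ECG generator: Gaussian-bump beat morphologies for the
# four MIT-BIH-style beat classes and RR-interval rhythm models for the four
# PhysioNet-2017-style record classes. Every output is fully determined by a
# single integer seed. All presets live in inst/extdata/presets.yaml.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

presets_env <- new.env(parent = emptyenv())

load_presets <- function() {
  if (is.null(presets_env$presets)) {
    path <- system.file("extdata", "presets.yaml", package = "lraecg")
    presets_env$presets <- yaml::read_yaml(path)
  }
  presets_env$presets
}

#' Beat morphology specification
#'
#' A beat is a sum of Gaussian bumps, one per ECG wave (P, Q, R, S, T and
#' class-specific variants), plus white Gaussian noise.
#'
#' @param class_label one of `"N"`, `"L"`, `"R"`, `"V"`.
#' @param waves data.frame with columns `wave` (name), `amp` (mV), `center`
#'   (s relative to the R peak) and `width` (Gaussian sigma, s; must be > 0).
#' @param noise_sd nonnegative white-noise standard deviation (mV).
#' @return an object of class `beat_morphology`.
#' @export
beat_morphology <- function(class_label, waves, noise_sd = 0.03) {
  stopifnot(is.data.frame(waves),
            all(c("wave", "amp", "center", "width") %in% names(waves)))
  if (any(waves$width <= 0)) stop("wave widths must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  structure(list(class_label = class_label, waves = waves, noise_sd = noise_sd),
            class = "beat_morphology")
}

#' Default beat morphologies for the four beat classes
#'
#' Reads the packaged preset file. The presets are constructed so that the
#' classes are separable by shape: V omits the P wave and has a main-peak
#' width at least 1.5x the N preset's; L carries a wide notched QRS, R an
#' rsR' double peak.
#'
#' @return named list of [beat_morphology()] objects (`N`, `L`, `R`, `V`).
#' @export
default_morphologies <- function() {
  p <- load_presets()$beat_morphologies
  lapply_names <- names(p)
  out <- lapply(lapply_names, function(cls) {
    waves <- do.call(rbind, lapply(p[[cls]]$waves, as.data.frame))
    beat_morphology(cls, waves, p[[cls]]$noise_sd)
  })
  stats::setNames(out, lapply_names)
}

# Noiseless analytic beat: sum of the morphology's Gaussian bumps on a
# length-d grid with the R peak at sample `pre` (0-based).
beat_template <- function(morph, d, fs, pre, p_scale = 1) {
  t <- (seq_len(d) - 1L - pre) / fs
  amps <- morph$waves$amp
  if (p_scale != 1) amps[morph$waves$wave == "P"] <- amps[morph$waves$wave == "P"] * p_scale
  y <- numeric(d)
  for (w in seq_along(amps)) {
    y <- y + amps[w] * exp(-0.5 * ((t - morph$waves$center[w]) / morph$waves$width[w])^2)
  }
  y
}

#' Synthesize one beat
#'
#' Samples the morphology's Gaussian bumps on a length-`d` grid with the R
#' peak at sample `pre`, then adds white Gaussian noise of the morphology's
#' `noise_sd`. Noise is drawn from the current RNG state (seed upstream, e.g.
#' via [synth_beat_dataset()], for determinism).
#'
#' @param morph a [beat_morphology()].
#' @param d segment length in samples.
#' @param fs sampling rate, Hz.
#' @param pre samples before the R peak (R sits at 0-based index `pre`).
#' @return numeric vector of length `d` (mV, not yet Z-scored).
#' @export
synth_beat <- function(morph, d = 250L, fs = 360, pre = 100L) {
  stopifnot(inherits(morph, "beat_morphology"), d >= 1L)
  y <- beat_template(morph, d, fs, pre)
  if (morph$noise_sd > 0) y <- y + stats::rnorm(d, 0, morph$noise_sd)
  y
}

#' Synthesize a labelled, Z-scored beat dataset
#'
#' Generates `n_per_class` beats for each of the four classes, Z-scores the
#' collection with its pooled mean and population standard deviation, and
#' shuffles the rows with the seeded generator. Pooled (rather than per-beat)
#' standardization follows the record-level Z-scoring convention used for
#' annotated records: it preserves the per-beat baseline and amplitude
#' differences that per-segment standardization would erase. Identical seeds
#' give identical datasets.
#'
#' @param n_per_class beats per class (>= 0).
#' @param d segment length in samples.
#' @param seed integer seed controlling noise and shuffling.
#' @param fs sampling rate, Hz.
#' @param pre samples before the R peak.
#' @param morphologies named list of four [beat_morphology()] presets, in
#'   label order.
#' @return a [beat_dataset()] with labels 0..3 and the MIT-BIH label map.
#' @export
synth_beat_dataset <- function(n_per_class, d = 250L, seed = 1L, fs = 360,
                               pre = 100L, morphologies = default_morphologies()) {
  stopifnot(n_per_class >= 0L, length(morphologies) == 4L)
  lmap <- stats::setNames(names(morphologies),
                          as.character(seq_along(morphologies) - 1L))
  if (n_per_class == 0L) {
    return(beat_dataset(matrix(numeric(0), 0L, d), integer(0), lmap,
                        provenance = data.frame(record_id = character(0),
                                                sample_index = integer(0))))
  }
  with_seed(seed, {
    segs <- matrix(0, 4L * n_per_class, d)
    labels <- integer(4L * n_per_class)
    row <- 1L
    for (cls in seq_along(morphologies)) {
      for (b in seq_len(n_per_class)) {
        segs[row, ] <- synth_beat(morphologies[[cls]], d, fs, pre)
        labels[row] <- cls - 1L
        row <- row + 1L
      }
    }
    mu <- mean(segs)
    sigma <- sqrt(mean((segs - mu)^2))
    segs <- (segs - mu) / sigma
    ord <- sample.int(nrow(segs))
    beat_dataset(segs[ord, , drop = FALSE], labels[ord], lmap,
                 provenance = data.frame(
                   record_id = sprintf("synthetic-seed%d", seed),
                   sample_index = ord - 1L))
  })
}

#' Rhythm strip specification
#'
#' @param class_label one of `"N"`, `"AF"`, `"Other"`, `"Noisy"`.
#' @param beat beat-class morphology name used for the strip's beats.
#' @param duration strip duration, s.
#' @param fs sampling rate, Hz.
#' @param mean_rr mean RR interval, s.
#' @param rr_model `"normal"` (Gaussian jitter of sd `jitter`) or `"uniform"`
#'   (uniform jitter of half-width `jitter`).
#' @param jitter RR jitter parameter, s.
#' @param p_scale P-wave amplitude multiplier (0 removes the P wave).
#' @param noise_sd additive white-noise sd, mV.
#' @return an object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(class_label, beat = "N", duration = 30, fs = 300,
                        mean_rr = 0.8, rr_model = c("normal", "uniform"),
                        jitter = 0.02, p_scale = 1, noise_sd = 0.02) {
  rr_model <- match.arg(rr_model)
  stopifnot(duration > 0, fs > 0, mean_rr > 0, jitter >= 0, noise_sd >= 0)
  if (floor(duration / mean_rr) < 1) {
    stop("duration and mean_rr must allow at least one beat", call. = FALSE)
  }
  structure(list(class_label = class_label, beat = beat, duration = duration,
                 fs = fs, mean_rr = mean_rr, rr_model = rr_model,
                 jitter = jitter, p_scale = p_scale, noise_sd = noise_sd),
            class = "rhythm_spec")
}

#' Default rhythm specifications for the four record classes
#'
#' Presets from the packaged config: `N` (regular sinus), `AF` (highly
#' irregular RR with uniform jitter and no P waves; its RR coefficient of
#' variation is several times the N preset's), `Other` (slow wide-complex
#' rhythm) and `Noisy` (sinus buried in noise; signal-to-noise ratio below
#' 0 dB).
#'
#' @return named list of [rhythm_spec()] objects.
#' @export
default_rhythm_specs <- function() {
  p <- load_presets()$rhythm_specs
  out <- lapply(names(p), function(cls) {
    s <- p[[cls]]
    rhythm_spec(cls, beat = s$beat, duration = s$duration, fs = s$fs,
                mean_rr = s$mean_rr, rr_model = s$rr_model, jitter = s$jitter,
                p_scale = s$p_scale, noise_sd = s$noise_sd)
  })
  stats::setNames(out, names(p))
}

#' Synthesize a rhythm strip record
#'
#' Places beats at RR intervals drawn from the spec's jitter model, adds white
#' noise, and returns an [ecg_record()]. The generator's internals are stored
#' as attributes for verification: `rr_intervals` (the drawn RR list, s),
#' `clean` (the noiseless component), `noise`, and `annotations`
#' (R-peak indices as [beat_annotations()], also used by [write_fixture()]).
#'
#' @param spec a [rhythm_spec()].
#' @param seed integer seed.
#' @param morphologies beat-morphology presets to draw from.
#' @return an `ecg_record` of length `duration * fs` samples.
#' @export
synth_rhythm_record <- function(spec, seed = 1L,
                                morphologies = default_morphologies()) {
  stopifnot(inherits(spec, "rhythm_spec"))
  morph <- morphologies[[spec$beat]]
  n <- as.integer(round(spec$duration * spec$fs))
  with_seed(seed, {
    rr <- numeric(0)
    t_peaks <- numeric(0)
    t_cur <- 0.4                       # first R peak 0.4 s into the strip
    repeat {
      if (t_cur > spec$duration - 0.4) break
      t_peaks <- c(t_peaks, t_cur)
      step <- switch(spec$rr_model,
        normal  = stats::rnorm(1L, spec$mean_rr, spec$jitter),
        uniform = stats::runif(1L, spec$mean_rr - spec$jitter,
                               spec$mean_rr + spec$jitter))
      step <- max(step, 0.25)          # refractory floor
      rr <- c(rr, step)
      t_cur <- t_cur + step
    }
    rr <- rr[-length(rr)]              # intervals between emitted peaks
    t <- (seq_len(n) - 1L) / spec$fs
    clean <- numeric(n)
    amps <- morph$waves$amp
    amps[morph$waves$wave == "P"] <- amps[morph$waves$wave == "P"] * spec$p_scale
    for (tp in t_peaks) {
      for (w in seq_along(amps)) {
        clean <- clean + amps[w] *
          exp(-0.5 * ((t - tp - morph$waves$center[w]) / morph$waves$width[w])^2)
      }
    }
    noise <- stats::rnorm(n, 0, spec$noise_sd)
    rec <- ecg_record(clean + noise, fs = spec$fs,
                      record_id = sprintf("synthetic-%s-seed%d",
                                          spec$class_label, seed))
    peak_idx <- as.integer(round(t_peaks * spec$fs))
    attr(rec, "rr_intervals") <- rr
    attr(rec, "clean") <- clean
    attr(rec, "noise") <- noise
    attr(rec, "annotations") <- beat_annotations(
      peak_idx, rep(morph$class_label, length(peak_idx)))
    rec
  })
}
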