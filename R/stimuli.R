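#' Parametric point-light walker trajectories
#'
#' Produces 12 joint trajectories (head, shoulders, elbows, wrists, hips,
#' knees, ankles) of a sagittal-view walking figure over two gait cycles,
#' from a simple sinusoidal gait model: limb joints swing in anti-phase
#' about their rest positions with amplitudes growing toward the
#' extremities, and the whole body bobs vertically at twice the stride
#' frequency. Not motion-capture realism — a structured, periodic carrier
#' for testing scrambling and noise-dot construction.
#'
#' @param n_frames Frames covering two gait cycles (default 60).
#' @return Tibble: `dot` (1–12), `frame`, `x`, `y` (arbitrary units,
#'   figure height ~2).
#' @export
walker_trajectories <- function(n_frames = 60L) {
  t <- seq(0, 4 * pi, length.out = n_frames)  # 2 cycles
  joint <- function(x0, y0, ax, phase) {
    tibble::tibble(frame = seq_len(n_frames),
                   x = x0 + ax * sin(t + phase),
                   y = y0 + 0.03 * cos(2 * t))  # vertical bob, 2x stride freq
  }
  spec <- tibble::tribble(
    ~name, ~x0, ~y0, ~ax, ~phase,
    "l_shoulder", -0.05, 1.6, 0.05, 0,
    "r_shoulder", 0.05, 1.6, 0.05, pi,
    "l_elbow", -0.08, 1.3, 0.12, 0,
    "r_elbow", 0.08, 1.3, 0.12, pi,
    "l_wrist", -0.10, 1.0, 0.22, 0,
    "r_wrist", 0.10, 1.0, 0.22, pi,
    "l_hip", -0.05, 1.0, 0.06, pi,
    "r_hip", 0.05, 1.0, 0.06, 0,
    "l_knee", -0.06, 0.5, 0.18, pi,
    "r_knee", 0.06, 0.5, 0.18, 0,
    "l_ankle", -0.07, 0.05, 0.30, pi,
    "r_ankle", 0.07, 0.05, 0.30, 0
  )
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    j <- joint(spec$x0[i], spec$y0[i], spec$ax[i], spec$phase[i])
    j$dot <- i
    j
  })
  dplyr::bind_rows(rows)[, c("dot", "frame", "x", "y")]
}

#' Build a biological-motion trial
#'
#' Assembles the dot set for one biological-motion trial from walker joint
#' trajectories. When `scrambled`, each dot keeps its own motion (its
#' frame-to-frame displacements, hence its speed profile) but is relocated
#' to a random start position, destroying the global body form while
#' matching local motion statistics. Noise dots are motion-matched: each
#' copies the displacement sequence of a randomly chosen walker dot under
#' a random circular time shift, from a random start position, so the
#' per-dot speed distribution of the noise equals that of the walker.
#'
#' @param joints Tibble from [walker_trajectories()] (12 dots).
#' @param n_noise_dots Number of noise dots; the task used 0, 10 or 30
#'   (other values are produced with a warning).
#' @param scrambled Scramble the walker dots' positions?
#' @param seed Optional integer seed.
#' @return Tibble: `dot`, `frame`, `x`, `y`, `kind` (`walker`/`noise`).
#' @export
make_walker_trial <- function(joints, n_noise_dots = 0L, scrambled = FALSE,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!n_noise_dots %in% c(0L, 10L, 30L)) {
    rlang::warn("n_noise_dots outside the task's {0, 10, 30} settings")
  }
  dots <- split(joints[order(joints$dot, joints$frame), ], joints$dot)
  span <- c(diff(range(joints$x)), diff(range(joints$y)))
  origin <- c(min(joints$x), min(joints$y))

  relocate <- function(df, keep_position) {
    if (keep_position) return(df)
    dx <- diff(df$x); dy <- diff(df$y)
    start <- origin + runif(2) * span
    df$x <- cumsum(c(start[1], dx))
    df$y <- cumsum(c(start[2], dy))
    df
  }
  walkers <- lapply(dots, relocate, keep_position = !scrambled)
  walkers <- dplyr::bind_rows(walkers)
  walkers$kind <- "walker"

  noise <- NULL
  if (n_noise_dots > 0) {
    mk_noise <- function(k) {
      src <- dots[[sample.int(length(dots), 1)]]
      dx <- diff(src$x); dy <- diff(src$y)
      shift <- sample.int(length(dx), 1)
      idx <- ((seq_along(dx) + shift - 1L) %% length(dx)) + 1L
      start <- origin + runif(2) * span
      tibble::tibble(dot = 12L + k, frame = src$frame,
                     x = cumsum(c(start[1], dx[idx])),
                     y = cumsum(c(start[2], dy[idx])),
                     kind = "noise")
    }
    noise <- dplyr::bind_rows(lapply(seq_len(n_noise_dots), mk_noise))
  }
  dplyr::bind_rows(walkers, noise)
}

#' Phase-morph and shear a grayscale object image
#'
#' Implements the object-invariance stimulus construction: the image's
#' Fourier phase is mixed with white-noise phase (unit phasors combined
#' with weights `1 - noise_weight` and `noise_weight`), recombined with a
#' fixed average magnitude spectrum by inverse Fourier transform, then
#' sheared horizontally by the skew factor and rescaled to `[0, 1]`.
#' With `noise_weight = 0`, `skew = 0` and the image's own magnitude
#' spectrum the input is reconstructed exactly.
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param average_magnitude Magnitude-spectrum matrix, same shape as
#'   `image` (typically the mean magnitude over the stimulus set).
#' @param noise_weight Phase-noise mixing weight in `[0, 1]` (default 0.5).
#' @param skew Horizontal shear factor in arbitrary units (the task used
#'   0, 1.4 and 2.3); a column offset of `skew/2.3 * 0.5` pixels per row
#'   off-centre, so skew 2.3 shifts the top and bottom rows by a quarter of
#'   the image height.
#' @param seed Optional seed for the noise phase.
#' @return Grayscale matrix in `[0, 1]`, same shape as the input.
#' @export
morph_object_image <- function(image, average_magnitude, noise_weight = 0.5,
                               skew = 0, seed = NULL) {
  if (!all(dim(image) == dim(average_magnitude))) {
    rlang::abort("image and average_magnitude must have the same shape")
  }
  stopifnot(noise_weight >= 0, noise_weight <= 1)
  if (!is.null(seed)) set.seed(seed)

  ph <- Arg(stats::fft(image))
  if (noise_weight > 0) {
    noise_ph <- Arg(stats::fft(matrix(runif(length(image)), nrow(image))))
    z <- (1 - noise_weight) * exp(1i * ph) + noise_weight * exp(1i * noise_ph)
    ph <- Arg(z)
  }
  rec <- Re(stats::fft(average_magnitude * exp(1i * ph), inverse = TRUE)) /
    length(image)

  out <- shear_horizontal(rec, skew)
  rng <- range(out)
  if (diff(rng) > 0) out <- (out - rng[1]) / diff(rng)
  out
}

# Horizontal shear: row r is shifted by slope * (r - centre) columns,
# linear interpolation, zero fill. slope = skew/2.3 * 0.5 columns/row, so
# the strongest task setting (2.3) tilts verticals by atan(0.5) ~ 27 deg.
shear_horizontal <- function(m, skew) {
  if (skew == 0) return(m)
  slope <- skew / 2.3 * 0.5
  nr <- nrow(m); nc <- ncol(m)
  centre <- (nr + 1) / 2
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    offset <- slope * (r - centre)
    src <- seq_len(nc) - offset
    lo <- floor(src); frac <- src - lo
    v_lo <- ifelse(lo >= 1 & lo <= nc, m[r, pmin(pmax(lo, 1), nc)], 0)
    hi <- lo + 1
    v_hi <- ifelse(hi >= 1 & hi <= nc, m[r, pmin(pmax(hi, 1), nc)], 0)
    v_lo[lo < 1 | lo > nc] <- 0
    v_hi[hi < 1 | hi > nc] <- 0
    out[r, ] <- (1 - frac) * v_lo + frac * v_hi
  }
  out
}

#' @rdname morph_object_image
#' @details `shear_slope(skew)` returns the column-per-row slope applied
#'   for a given skew setting.
#' @export
shear_slope <- function(skew) skew / 2.3 * 0.5
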