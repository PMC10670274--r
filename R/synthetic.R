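#' Synthetic cohort specification
#'
#' Parameter bundle for the synthetic cohort generator. The defaults emulate
#' the analyzable study cohort: 395 cases, age 63.12 +/- 10.16 y,
#' BMI 24.09 +/- 4.45 kg/m^2, CT-DXA interval 7.13 +/- 6.12 days,
#' 115/248 male fraction. Each case carries a latent texture triple
#' (muscle base HU, interior noise sd, spatial correlation length in pixels);
#' the four DXA targets (total lumbar BMC/BMD, total hip BMC/BMD) are linear
#' in the latent triple plus a per-target intercept and Gaussian noise, so
#' downstream regressions have a known recoverable truth.
#'
#' @param n_cases number of cases (>= 1).
#' @param age_mean_sd,bmi_mean_sd,interval_mean_sd length-2 `(mean, sd)`;
#'   age is truncated to `[18, 100]` y, BMI to `[12, 60]` kg/m^2, interval to
#'   nonnegative days.
#' @param sex_ratio fraction male in `[0, 1]`.
#' @param exclusion_rates length-5 per-flag probabilities (no measurable
#'   T12-S1 cut; compression/burst fracture; vertebroplasty/kyphoplasty;
#'   metal artifact; osteolytic change). Default 0: the emulated cohort is
#'   the post-exclusion one.
#' @param image_size pixels per side of each rendered slice (>= 16).
#' @param texture_params list of length-2 uniform ranges `base_hu` (HU),
#'   `noise_sd` (HU), `corr_len` (pixels).
#' @param truth_weights 4 x 3 matrix, one row per target (lumbar BMC, lumbar
#'   BMD, hip BMC, hip BMD), one column per latent parameter.
#' @param truth_bias length-4 per-target intercept (g or g/cm^2).
#' @param truth_noise_sd length-4 per-target Gaussian noise sd (>= 0).
#' @param seed integer RNG seed; the full cohort is bit-reproducible from it.
#' @return Object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_cases = 395L,
                        age_mean_sd = c(63.12, 10.16),
                        bmi_mean_sd = c(24.09, 4.45),
                        interval_mean_sd = c(7.13, 6.12),
                        sex_ratio = 115 / 248,
                        exclusion_rates = rep(0, 5),
                        image_size = 64L,
                        texture_params = list(base_hu = c(20, 70),
                                              noise_sd = c(5, 25),
                                              corr_len = c(0.8, 2.5)),
                        truth_weights = default_truth_weights(),
                        truth_bias = c(50, 0.40, 25, 0.45),
                        truth_noise_sd = c(1.2, 0.17, 0.67, 0.16),
                        seed = 1L) {
  if (!is.numeric(n_cases) || n_cases < 1) stop_field("n_cases", "must be >= 1")
  for (nm in c("age_mean_sd", "bmi_mean_sd", "interval_mean_sd")) {
    v <- get(nm)
    if (length(v) != 2L || v[2] < 0) stop_field(nm, "must be (mean, sd) with sd >= 0")
  }
  if (sex_ratio < 0 || sex_ratio > 1) stop_field("sex_ratio", "must be in [0, 1]")
  if (length(exclusion_rates) != 5L || any(exclusion_rates < 0 | exclusion_rates > 1)) {
    stop_field("exclusion_rates", "must be 5 probabilities in [0, 1]")
  }
  if (image_size < 16) stop_field("image_size", "must be >= 16")
  for (nm in c("base_hu", "noise_sd", "corr_len")) {
    v <- texture_params[[nm]]
    if (is.null(v) || length(v) != 2L || v[1] > v[2]) {
      stop_field(paste0("texture_params$", nm), "must be (low, high) with low <= high")
    }
  }
  if (texture_params$noise_sd[1] < 0) stop_field("texture_params$noise_sd", "must be >= 0")
  if (texture_params$corr_len[1] <= 0) stop_field("texture_params$corr_len", "must be > 0")
  truth_weights <- as.matrix(truth_weights)
  if (!all(dim(truth_weights) == c(4L, 3L))) {
    stop_field("truth_weights", "must be a 4 x 3 matrix (targets x latent params)")
  }
  if (length(truth_bias) != 4L) stop_field("truth_bias", "must have 4 entries")
  if (length(truth_noise_sd) != 4L || any(truth_noise_sd < 0)) {
    stop_field("truth_noise_sd", "must be 4 nonnegative sds")
  }
  structure(
    list(n_cases = as.integer(n_cases), age_mean_sd = age_mean_sd,
         bmi_mean_sd = bmi_mean_sd, interval_mean_sd = interval_mean_sd,
         sex_ratio = sex_ratio, exclusion_rates = exclusion_rates,
         image_size = as.integer(image_size), texture_params = texture_params,
         truth_weights = truth_weights, truth_bias = as.numeric(truth_bias),
         truth_noise_sd = as.numeric(truth_noise_sd), seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Default latent-to-DXA truth weights
#'
#' Rows: lumbar BMC (g), lumbar BMD (g/cm^2), hip BMC (g), hip BMD (g/cm^2);
#' columns: muscle base HU, interior noise sd, correlation length. Together
#' with the default intercepts and noise sds these put the targets on
#' clinically plausible scales (lumbar BMC around 55 g, BMDs around
#' 1.05 g/cm^2) with a latent-level signal-to-noise giving moderate-to-strong
#' texture-DXA correlations.
#'
#' @return 4 x 3 numeric matrix with dimnames.
#' @export
default_truth_weights <- function() {
  w <- rbind(
    lumbar_bmc = c(0.09, 0.02, 0.40),
    lumbar_bmd = c(0.013, 0.003, 0.04),
    hip_bmc    = c(0.05, 0.01, 0.30),
    hip_bmd    = c(0.012, 0.002, 0.04)
  )
  colnames(w) <- c("base_hu", "noise_sd", "corr_len")
  w
}

dxa_target_names <- c("lumbar_bmc", "lumbar_bmd", "hip_bmc", "hip_bmd")
exclusion_flag_names <- c("no_axial_cut", "fracture", "vertebro_kypho",
                          "metal_artifact", "osteolytic")

#' Render one textured pseudo-CT slice
#'
#' Draws a muscle-like blob (a filled ellipse-like region whose radius is
#' modulated by random low-order harmonics, so the boundary is irregular and
#' the mask non-rectangular) on a fat-range background (-100 HU with mild
#' noise). The blob interior is `base_hu` plus a correlated Gaussian field:
#' white noise convolved with a Gaussian kernel of sd `corr_len` pixels and
#' scaled so each interior pixel has marginal sd `noise_sd` exactly.
#'
#' @param latent named numeric: `base_hu`, `noise_sd`, `corr_len`.
#' @param image_size pixels per side (>= 16).
#' @param side `"left"` or `"right"`.
#' @param seed RNG seed for this slice.
#' @return A [ct_slice()] with attributes `annotation` (a drawn-region
#'   polygon enclosing the blob, two-column `(row, col)` matrix) and
#'   `interior` (the logical blob mask).
#' @export
render_slice <- function(latent, image_size, side = c("left", "right"), seed = 1L) {
  side <- match.arg(side)
  if (image_size < 16) stop_field("image_size", "must be >= 16")
  latent <- unlist(latent)[c("base_hu", "noise_sd", "corr_len")]
  if (any(is.na(latent))) {
    stop_field("latent", "needs base_hu, noise_sd and corr_len")
  }
  if (latent[["corr_len"]] <= 0) stop_field("corr_len", "must be positive")
  if (latent[["noise_sd"]] < 0) stop_field("noise_sd", "must be >= 0")
  n <- as.integer(image_size)
  with_seed(seed, {
    # irregular blob boundary: radius modulated by 4 random harmonics
    cr <- (n - 1) / 2
    cc <- (n - 1) / 2 + if (side == "left") -0.04 * n else 0.04 * n
    r0 <- 0.30 * n
    amp <- stats::runif(4, 0, 0.08)
    phase <- stats::runif(4, 0, 2 * pi)
    theta <- seq(0, 2 * pi, length.out = 49L)[-49L]
    radius <- r0 * (1 + colSums(amp * sin(outer(1:4, theta) + phase)))
    poly_r <- cr + radius * sin(theta)
    poly_c <- cc + radius * cos(theta)
    pr <- rep(0:(n - 1L), times = n)
    pc <- rep(0:(n - 1L), each = n)
    interior <- matrix(point_in_polygon(pr, pc, poly_r, poly_c), n, n)

    pixels <- matrix(-100 + 4 * stats::rnorm(n * n), n, n)  # fat background
    field <- correlated_field(n, latent[["corr_len"]])
    pixels[interior] <- latent[["base_hu"]] +
      latent[["noise_sd"]] * field[interior]

    # hand-drawn-style annotation: slightly dilated boundary polygon
    ann <- cbind(row = cr + 1.12 * radius * sin(theta),
                 col = cc + 1.12 * radius * cos(theta))
    sl <- ct_slice(pixels, side = side)
    attr(sl, "annotation") <- ann
    attr(sl, "interior") <- interior
    sl
  })
}

# Stationary correlated Gaussian field: white noise on a padded grid
# convolved with a separable Gaussian kernel normalized so every output pixel
# is exactly N(0, 1) marginally.
correlated_field <- function(n, corr_len) {
  rad <- max(1L, ceiling(3 * corr_len))
  g <- exp(-0.5 * ((-rad):rad / corr_len)^2)
  g <- g / sqrt(sum(g^2))
  np <- n + 2L * rad
  w <- matrix(stats::rnorm(np * np), np, np)
  # banded n x np convolution operator
  B <- matrix(0, n, np)
  for (i in seq_len(n)) B[i, i:(i + 2L * rad)] <- g
  B %*% w %*% t(B)
}

#' Generate a synthetic cohort
#'
#' Draws metadata from the spec's truncated normal distributions, samples the
#' latent texture triple per case (uniform over the spec ranges; shared by the
#' two sides of a case), renders a left and right slice per case, and sets
#' each DXA target to `truth_bias + truth_weights . latent + N(0,
#' truth_noise_sd)`. Exclusion flags are independent Bernoulli draws. The
#' whole cohort is bit-reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param render if `FALSE`, skip slice rendering (metadata, latents and DXA
#'   only) — handy for large distribution checks.
#' @return Object of class `mfx_cohort`: a list of `synthetic_case` objects
#'   with the spec and target names as attributes. Each case holds `case_id`,
#'   `left`/`right` slices, `dxa` (named length-4), `metadata`,
#'   `exclusion_flags` and `latent`.
#' @export
generate_cohort <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_cases
  with_seed(spec$seed, {
    age <- rnorm_trunc(n, spec$age_mean_sd[1], spec$age_mean_sd[2], 18, 100)
    bmi <- rnorm_trunc(n, spec$bmi_mean_sd[1], spec$bmi_mean_sd[2], 12, 60)
    interval <- rnorm_trunc(n, spec$interval_mean_sd[1], spec$interval_mean_sd[2], 0, Inf)
    sex <- ifelse(stats::runif(n) < spec$sex_ratio, "M", "F")
    flags <- sapply(spec$exclusion_rates,
                    function(p) stats::runif(n) < p)  # n x 5
    flags <- matrix(flags, nrow = n, ncol = 5L,
                    dimnames = list(NULL, exclusion_flag_names))
    tp <- spec$texture_params
    latent <- cbind(
      base_hu = stats::runif(n, tp$base_hu[1], tp$base_hu[2]),
      noise_sd = stats::runif(n, tp$noise_sd[1], tp$noise_sd[2]),
      corr_len = stats::runif(n, tp$corr_len[1], tp$corr_len[2])
    )
    noise <- sapply(spec$truth_noise_sd, function(s) stats::rnorm(n, 0, s))
    noise <- matrix(noise, nrow = n, ncol = 4L)
    dxa <- sweep(latent %*% t(spec$truth_weights), 2, spec$truth_bias, "+") + noise
    colnames(dxa) <- dxa_target_names
    if (any(dxa <= 0)) {
      stop("generated DXA values are not strictly positive; reduce truth_noise_sd or adjust truth_weights/truth_bias",
           call. = FALSE)
    }
    # CT acquisition dates over the study window; DXA follows by `interval`
    ct_date <- as.Date("2012-05-06") +
      floor(stats::runif(n, 0, as.numeric(as.Date("2021-11-30") - as.Date("2012-05-06")) + 1))
    render_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n), ncol = 2L)

    cases <- vector("list", n)
    for (i in seq_len(n)) {
      left <- right <- NULL
      if (render) {
        left <- render_slice(latent[i, ], spec$image_size, "left", render_seeds[i, 1])
        right <- render_slice(latent[i, ], spec$image_size, "right", render_seeds[i, 2])
      }
      cases[[i]] <- structure(
        list(case_id = sprintf("case_%04d", i),
             left = left, right = right,
             dxa = dxa[i, ],
             metadata = list(age = age[i], sex = sex[i], bmi = bmi[i],
                             interval_days = interval[i],
                             ct_date = ct_date[i],
                             dxa_date = ct_date[i] + round(interval[i])),
             exclusion_flags = flags[i, ],
             latent = latent[i, ]),
        class = "synthetic_case"
      )
    }
    structure(cases, class = "mfx_cohort", spec = spec,
              targets = dxa_target_names)
  })
}

#' Tabulate cohort metadata
#'
#' @param cohort an [generate_cohort()] result.
#' @return data.frame with one row per case: `case_id`, demographics, dates,
#'   the five exclusion flags (`flag_*`), latent parameters (`latent_*`) and
#'   DXA targets.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "mfx_cohort"))
  rows <- lapply(cohort, function(cs) {
    md <- cs$metadata
    out <- data.frame(case_id = cs$case_id, age = md$age, sex = md$sex,
                      bmi = md$bmi, interval_days = md$interval_days,
                      ct_date = md$ct_date, dxa_date = md$dxa_date,
                      stringsAsFactors = FALSE)
    for (f in exclusion_flag_names) out[[paste0("flag_", f)]] <- unname(cs$exclusion_flags[f])
    for (l in colnames(attr(cohort, "spec")$truth_weights)) {
      out[[paste0("latent_", l)]] <- unname(cs$latent[l])
    }
    for (t in dxa_target_names) out[[t]] <- unname(cs$dxa[t])
    out
  })
  do.call(rbind, rows)
}

#' Write a cohort to disk
#'
#' Writes `cohort.csv` (metadata + DXA table), `truth.json` (truth weights,
#' bias, noise sds and seed) and, when slices are rendered, one plain-text
#' CSV array of HU values per slice under `slices/`.
#'
#' @param cohort an [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param write_slices write the per-slice arrays (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_slices = TRUE) {
  stopifnot(inherits(cohort, "mfx_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort_table(cohort), file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  spec <- attr(cohort, "spec")
  write_json_file(
    list(targets = dxa_target_names,
         latent_params = colnames(spec$truth_weights),
         truth_weights = apply(spec$truth_weights, 1, as.numeric, simplify = FALSE),
         truth_bias = spec$truth_bias, truth_noise_sd = spec$truth_noise_sd,
         seed = spec$seed),
    file.path(dir, "truth.json")
  )
  if (write_slices && !is.null(cohort[[1]]$left)) {
    sdir <- file.path(dir, "slices")
    dir.create(sdir, showWarnings = FALSE)
    for (cs in cohort) {
      for (side in c("left", "right")) {
        utils::write.table(
          round(cs[[side]]$pixels, 2),
          file.path(sdir, sprintf("%s_%s.csv", cs$case_id, side)),
          sep = ",", row.names = FALSE, col.names = FALSE
        )
      }
    }
  }
  invisible(dir)
}

#' Simulate a feature-level regression cohort with sparse linear truth
#'
#' Generates a design matrix of independent standard-normal features and a
#' response `y = X w + b + N(0, sigma)` with `n_active` nonzero unit weights.
#' `sigma` is set from the requested population R^2
#' (`sigma^2 = n_active (1 - r2) / r2`); `r2 = 1` gives a noiseless cohort.
#' This is the regression-layer analogue of the image cohort, used for
#' parameter-recovery and cross-validation studies at the study scale
#' (n = 395, J = 90).
#'
#' @param n cases; @param J features; @param n_active nonzero truth weights;
#' @param r2 population R^2 in (0, 1]; @param bias intercept; @param seed RNG seed.
#' @return list with `X`, `y`, `w_true`, `bias`, `noise_sd`.
#' @export
simulate_regression_cohort <- function(n, J, n_active = 5L, r2 = 0.5,
                                       bias = 1, seed = 1L) {
  stopifnot(n >= 2, J >= 1, n_active >= 0, n_active <= J, r2 > 0, r2 <= 1)
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * J), n, J,
                dimnames = list(NULL, paste0("f", seq_len(J))))
    w <- numeric(J)
    if (n_active > 0) w[seq_len(n_active)] <- 1
    noise_sd <- if (r2 < 1) sqrt(n_active * (1 - r2) / r2) else 0
    y <- as.vector(X %*% w) + bias + stats::rnorm(n, 0, noise_sd)
    list(X = X, y = y, w_true = w, bias = bias, noise_sd = noise_sd)
  })
}
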