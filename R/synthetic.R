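#' Published correlation structure of rumen nutritional constituents
#'
#' The 7 x 7 Pearson correlation matrix among ash, lignin, microbial N,
#' available protein (AP_R), cellulose, hemicellulose and TNC2+lipids
#' (\% of dry matter) measured across 481 winter rumen samples, as printed.
#' The printed matrix is very slightly indefinite (smallest eigenvalue about
#' -3e-4, a rounding artifact); [repair_correlation()] projects it back onto
#' the positive semi-definite cone when a generator needs a factorizable
#' target.
#'
#' @return Named 7 x 7 symmetric matrix with unit diagonal.
#' @export
rumen_correlation_targets <- function() {
  nm <- c("ash", "lignin", "microbial_n", "ap", "cellulose",
          "hemicellulose", "tnc2_lipids")
  R <- diag(7)
  dimnames(R) <- list(nm, nm)
  lower <- list(
    c("lignin", "ash", 0.783),
    c("microbial_n", "ash", 0.536), c("microbial_n", "lignin", 0.798),
    c("ap", "ash", 0.750), c("ap", "lignin", 0.956),
    c("ap", "microbial_n", 0.853),
    c("cellulose", "ash", -0.886), c("cellulose", "lignin", -0.962),
    c("cellulose", "microbial_n", -0.752), c("cellulose", "ap", -0.938),
    c("hemicellulose", "ash", -0.658), c("hemicellulose", "lignin", -0.786),
    c("hemicellulose", "microbial_n", -0.669),
    c("hemicellulose", "ap", -0.796),
    c("hemicellulose", "cellulose", 0.780),
    c("tnc2_lipids", "ash", 0.720), c("tnc2_lipids", "lignin", 0.696),
    c("tnc2_lipids", "microbial_n", 0.482), c("tnc2_lipids", "ap", 0.640),
    c("tnc2_lipids", "cellulose", -0.805),
    c("tnc2_lipids", "hemicellulose", -0.802))
  for (e in lower) {
    R[e[1], e[2]] <- R[e[2], e[1]] <- as.numeric(e[3])
  }
  R
}

#' Repair a correlation matrix to positive semi-definiteness
#'
#' Eigenvalue clipping: negative eigenvalues are floored at \code{eps}, the
#' matrix is reassembled and rescaled to unit diagonal.  A matrix that is
#' already positive semi-definite is returned unchanged.
#'
#' @param R Symmetric correlation matrix.
#' @param eps Eigenvalue floor.
#' @return Positive semi-definite correlation matrix.
#' @export
repair_correlation <- function(R, eps = 1e-6) {
  if (!isSymmetric(unname(R))) stop("R must be symmetric", call. = FALSE)
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eps) return(R)
  v <- pmax(e$values, eps)
  R2 <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / (d %o% d)
  dimnames(R2) <- dimnames(R)
  R2
}

#' Observed rumen range box in RMT coordinates
#'
#' Per-axis ranges of the 481 rumen samples in RMT space, as a reference
#' envelope: available protein 7--36\%, TNC2+lipids 24--48\%, fiber
#' 16--69\% of total macronutrients.
#'
#' @return Matrix with rows min/max and columns x (TNC2+lipids),
#'   y (AP_R), i (fiber).
#' @export
rumen_range_box <- function() {
  matrix(c(24, 48, 7, 36, 16, 69), nrow = 2,
         dimnames = list(c("min", "max"), c("x", "y", "i")))
}

#' Parameters of the synthetic rumen-sample generator
#'
#' Bundles every knob of [gen_rumen_samples()] with defaults emulating the
#' field study's conditions: 481 samples over 30 subpopulations in 7
#' management areas, the published constituent correlation matrix as target,
#' marginal means placing the composition inside the observed RMT envelope,
#' diet-type contrasts in lignin and microbial N, the observed age-sex mix,
#' and a 70:30 early:late sampling-date split (inverted in area A).
#'
#' Marginal dispersions are calibrated so that, with TNC2+lipids arising by
#' compositional subtraction, the induced TNC2 correlations reproduce the
#' printed row (see the methods vignette).
#'
#' @param n_samples Number of rumen samples.
#' @param target_correlation 7 x 7 correlation target over (ash, lignin,
#'   microbial_n, ap, cellulose, hemicellulose, tnc2_lipids); only the 6 x 6
#'   measured block is factorized, the TNC2 row emerges from closure.
#' @param marginal_means,marginal_sds Named vectors (\% of dry matter) for
#'   the six measured constituents.
#' @param diet_type_probs Named probabilities for broadleaf, shrub_sugar,
#'   conifer diet types (sum to 1).
#' @param diet_effects Data frame of per-type target means for \code{lignin}
#'   and \code{microbial_n} (\% of dm); realized by latent-score assignment,
#'   see Details.
#' @param n_subpops Number of subpopulations (moose management units).
#' @param min_per_subpop Minimum samples per subpopulation.
#' @param agesex_probs Named 6-vector of age-sex class probabilities.
#' @param calf_bm_mean,calf_bm_sd Calf dressed body mass, kg.
#' @param digestible_n_fraction Fraction of total N that is available
#'   (ADF-bound N is the complement).
#' @param early_late_split Proportion of samples dated in early winter
#'   (mid-October to November); area A uses the complement.
#' @param bm_ratio_slope Optional injected subpopulation-level slope of mean
#'   calf body mass (kg) per unit balance ratio; 0 (the null) by default.
#' @param range_box Optional RMT range box (see [rumen_range_box()]); when
#'   \code{range_box_filter} is TRUE, samples projecting outside it are
#'   rejected and redrawn.  Off by default: truncation distorts the target
#'   correlation structure.
#' @param range_box_filter Apply the range-box rejection filter.
#' @return List of class \code{synthetic_params}.
#'
#' @details Diet types are assigned by thresholding a latent score aligned
#' with the lignin and microbial-N axes of the latent composition: the
#' shrub-and-sugar type is the upper tail of that score, the remaining
#' samples split between broadleaf and conifer at random.  The score
#' direction and its noise admixture are solved analytically from the
#' requested per-type contrasts, so the printed type means emerge without
#' perturbing the pooled correlation structure (additive type shifts would
#' be incompatible with the strong printed correlations; see the methods
#' vignette).
#' @export
synthetic_params <- function(
    n_samples = 481,
    target_correlation = rumen_correlation_targets(),
    marginal_means = c(ash = 6, lignin = 16.6, microbial_n = 0.7715,
                       ap = 13.5, cellulose = 23, hemicellulose = 16),
    marginal_sds = c(ash = 0.862, lignin = 1.355, microbial_n = 0.25,
                     ap = 2.673, cellulose = 4.885, hemicellulose = 1.5),
    diet_type_probs = c(broadleaf = 0.5, shrub_sugar = 0.3, conifer = 0.2),
    diet_effects = data.frame(
      diet_type = c("broadleaf", "shrub_sugar", "conifer"),
      lignin = c(16, 18, 16),
      microbial_n = c(0.71, 0.92, 0.70)),
    n_subpops = 30,
    min_per_subpop = 5,
    agesex_probs = c(calf_f = 86, calf_m = 101, yearling_f = 28,
                     yearling_m = 21, adult_f = 67, adult_m = 47) / 350,
    calf_bm_mean = 65, calf_bm_sd = 8,
    digestible_n_fraction = 0.8,
    early_late_split = 0.7,
    bm_ratio_slope = 0,
    range_box = rumen_range_box(),
    range_box_filter = FALSE) {
  stopifnot(n_samples >= 1, n_subpops >= 1,
            abs(sum(diet_type_probs) - 1) < 1e-8,
            abs(sum(agesex_probs) - 1) < 1e-8,
            digestible_n_fraction > 0, digestible_n_fraction <= 1)
  cn <- c("ash", "lignin", "microbial_n", "ap", "cellulose", "hemicellulose")
  stopifnot(all(cn %in% names(marginal_means)),
            all(cn %in% names(marginal_sds)))
  out <- list(n_samples = n_samples,
              target_correlation = repair_correlation(target_correlation),
              marginal_means = marginal_means[cn],
              marginal_sds = marginal_sds[cn],
              diet_type_probs = diet_type_probs,
              diet_effects = diet_effects,
              n_subpops = n_subpops, min_per_subpop = min_per_subpop,
              agesex_probs = agesex_probs,
              calf_bm_mean = calf_bm_mean, calf_bm_sd = calf_bm_sd,
              digestible_n_fraction = digestible_n_fraction,
              early_late_split = early_late_split,
              bm_ratio_slope = bm_ratio_slope,
              range_box = range_box,
              range_box_filter = range_box_filter)
  class(out) <- "synthetic_params"
  out
}

#' Generate synthetic rumen samples with the study's statistical structure
#'
#' Draws latent multivariate-normal compositions for the six measured
#' constituents from the target correlation structure, derives TNC2+lipids
#' by compositional subtraction (so the closure
#' \code{ap + ndf + ash + tnc2_lipids = 100} holds by construction), assigns
#' diet types by latent-score thresholding, attaches subpopulation,
#' management-area, age-sex, date and body-mass metadata, and back-computes
#' the proximate-analysis record (total N, ADF-N, NDF, ADF, purine marker)
#' that [derive_profiles()] would turn into the same profile.
#'
#' @param params A [synthetic_params()] object.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return List with \code{records} (proximate records + metadata, the
#'   standard input format), \code{samples} (derived per-sample table:
#'   constituents, RMT coordinates, balance ratio, metadata) and
#'   \code{subpops} (the subpopulation table from
#'   [gen_subpop_structure()]).
#' @export
gen_rumen_samples <- function(params = synthetic_params(), seed) {
  stopifnot(inherits(params, "synthetic_params"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  with_seed(seed, {
    n <- params$n_samples
    X <- draw_constituents(params, n)
    if (params$range_box_filter) {
      for (tries in 1:20) {
        keep <- in_range_box(X, params$range_box)
        if (all(keep)) break
        X[!keep, ] <- draw_constituents(params, sum(!keep))
      }
      X <- X[in_range_box(X, params$range_box), , drop = FALSE]
      n <- nrow(X)
    }
    diet <- assign_diet_types(X, params)
    subpops <- gen_subpop_structure_impl(params)
    mmu <- assign_subpops(diet, subpops, params$min_per_subpop)

    tnc2 <- 100 - rowSums(X[, c("ash", "lignin", "ap", "cellulose",
                                "hemicellulose")])
    if (any(tnc2 <= 0)) {
      stop("infeasible marginals: closure leaves no room for TNC2+lipids",
           call. = FALSE)
    }
    if (params$bm_ratio_slope != 0) {
      # inject a subpopulation-level body-mass response to the balance ratio
      ratio_i <- X[, "ap"] / tnc2
      mr <- tapply(ratio_i, mmu, mean)
      dev <- as.numeric(mr[subpops$mmu]) - mean(ratio_i)
      dev[is.na(dev)] <- 0
      subpops$bm_offset <- subpops$bm_offset + params$bm_ratio_slope * dev
    }
    meta <- draw_metadata(n, subpops[match(mmu, subpops$mmu), ], params)
    samples <- data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      as.data.frame(X), tnc2_lipids = tnc2,
      diet_type = diet, mmu = mmu,
      mma = subpops$mma[match(mmu, subpops$mmu)],
      meta, stringsAsFactors = FALSE)
    samples$fiber <- samples$cellulose + samples$hemicellulose
    rmt <- rmt_points(samples)
    samples$x <- rmt$x; samples$y <- rmt$y; samples$i <- rmt$i
    samples$ratio <- samples$y / samples$x

    avail_n <- samples$ap / N_TO_PROTEIN
    total_n <- avail_n / params$digestible_n_fraction
    records <- data.frame(
      sample_id = samples$sample_id,
      ash = samples$ash,
      total_n = total_n,
      adf_n = total_n - avail_n,
      ndf = samples$lignin + samples$cellulose + samples$hemicellulose,
      adf = samples$lignin + samples$cellulose,
      lignin = samples$lignin,
      purine_marker = samples$microbial_n / PURINE_TO_MICROBIAL_N,
      mma = samples$mma, mmu = samples$mmu,
      age_class = samples$age_class, sex = samples$sex,
      body_mass = samples$body_mass, date = samples$date,
      diet_type = samples$diet_type,
      stringsAsFactors = FALSE)
    list(records = records, samples = samples, subpops = subpops,
         seed = seed)
  })
}

#' Generate the subpopulation (management-unit) table
#'
#' Thirty subpopulations spread over seven management areas (A--G), each
#' subpopulation carrying a diet-type label: management units are allocated
#' to diet types in the observed 16:8:6 broadleaf : shrub-and-sugar :
#' conifer proportion, with the conifer units in areas A and C, the
#' shrub-and-sugar units concentrated in G, and the broadleaf units in B,
#' D, E, F.
#'
#' @param params A [synthetic_params()] object.
#' @param seed Integer seed.
#' @return Data frame: \code{mmu}, \code{mma}, \code{diet_type},
#'   \code{bm_offset} (subpopulation deviation in mean calf body mass, kg).
#' @export
gen_subpop_structure <- function(params = synthetic_params(), seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  with_seed(seed, gen_subpop_structure_impl(params))
}

gen_subpop_structure_impl <- function(params) {
  k <- params$n_subpops
  # diet-type allocation proportional to the observed MMU counts (16:8:6)
  alloc <- round(k * c(broadleaf = 16, shrub_sugar = 8, conifer = 6) / 30)
  while (sum(alloc) > k) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1
  while (sum(alloc) < k) alloc[which.min(alloc)] <- alloc[which.min(alloc)] + 1
  mma_pool <- list(broadleaf = c("B", "D", "E", "F"),
                   shrub_sugar = c("G", "D", "E"),
                   conifer = c("A", "C"))
  rows <- do.call(rbind, lapply(names(alloc), function(dt) {
    if (alloc[dt] == 0) return(NULL)
    data.frame(diet_type = dt,
               mma = rep_len(mma_pool[[dt]], alloc[dt]),
               stringsAsFactors = FALSE)
  }))
  rows$mmu <- sprintf("%s-%02d", rows$mma, seq_len(nrow(rows)))
  rows$bm_offset <- rnorm(nrow(rows), 0, 4)
  rows[, c("mmu", "mma", "diet_type", "bm_offset")]
}

#' Generate synthetic reflectance spectra from composition profiles
#'
#' Emulates a near-infrared reflectance instrument at desk scale: each
#' sample's spectrum is a linear mixture of one non-negative component
#' spectrum per constituent, weighted by the constituent fractions, plus a
#' smooth baseline and Gaussian noise.  The default wavelength grid spans
#' 780--2498 nm at 4 nm (far coarser than a real instrument's 0.5 nm, which
#' matters for realism but not for testing the calibration contract).
#'
#' @param profiles Data frame or matrix of constituent fractions (\% of dry
#'   matter), one column per constituent.
#' @param basis_bank Matrix of component spectra (constituents x
#'   wavelengths), non-negative, rownames matching the profile columns.
#'   Defaults to a deterministic bank of smooth absorption-band bumps.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed.
#' @return Matrix samples x wavelengths, with wavelength column names.
#' @export
gen_spectra <- function(profiles, basis_bank = NULL, noise_sd = 0.002,
                        seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  C <- as.matrix(as.data.frame(profiles))
  if (is.null(basis_bank)) basis_bank <- default_basis_bank(colnames(C))
  if (!all(colnames(C) %in% rownames(basis_bank))) {
    stop("basis_bank lacks component spectra for: ",
         paste(setdiff(colnames(C), rownames(basis_bank)), collapse = ", "),
         call. = FALSE)
  }
  B <- basis_bank[colnames(C), , drop = FALSE]
  if (any(B < 0)) stop("component spectra must be non-negative", call. = FALSE)
  with_seed(seed, {
    wl <- as.numeric(colnames(B))
    baseline <- 0.1 + 0.05 * (wl - min(wl)) / diff(range(wl))
    S <- (C / 100) %*% B
    S <- sweep(S, 2, baseline, "+")
    S + matrix(rnorm(length(S), 0, noise_sd), nrow(S))
  })
}

#' Deterministic bank of synthetic component spectra
#'
#' One smooth, non-negative pseudo-absorption spectrum per constituent,
#' built from fixed Gaussian bands so the bank is identical across calls
#' and platforms.
#'
#' @param constituents Character vector of constituent names.
#' @param wavelengths Numeric grid in nm.
#' @return Matrix constituents x wavelengths with wavelength colnames.
#' @export
default_basis_bank <- function(constituents,
                               wavelengths = seq(780, 2498, by = 4)) {
  bank <- t(vapply(seq_along(constituents), function(k) {
    centers <- 780 + ((k * c(397, 811, 1201) + c(131, 59, 17) * k^2) %% 1719)
    widths <- 60 + 25 * ((k * c(3, 5, 7)) %% 4)
    heights <- 0.5 + 0.5 * (((k + 1:3) * 7919) %% 100) / 100
    colSums(heights * exp(-outer(centers, wavelengths, "-")^2 /
                            (2 * widths^2)))
  }, numeric(length(wavelengths))))
  dimnames(bank) <- list(constituents, wavelengths)
  bank
}

#' Simulate standardized balance pairs with a known slope
#'
#' Draws n standardized-scale pairs whose population OLS slope is exactly
#' \code{slope}: \code{x ~ N(0, 1)} and
#' \code{y = slope * x + sqrt(1 - slope^2) * e}.  Used for known-truth
#' recovery checks of the scaling regression (|slope| < 1).  With
#' \code{sd_ratio} supplied, x is rescaled so the population slope is
#' \code{slope / sd_ratio} while the correlation stays \code{slope} --
#' e.g. \code{sd_ratio = slope} gives true slope 1 at correlation
#' \code{slope}, the null of the isometry test.
#'
#' @param n Number of pairs.
#' @param slope Target population correlation (and slope on the
#'   standardized scale), |slope| < 1.
#' @param seed Integer seed.
#' @param sd_ratio Optional x standard deviation (default 1).
#' @return Data frame with columns \code{x}, \code{y}.
#' @export
gen_balance_pairs <- function(n, slope, seed, sd_ratio = 1) {
  stopifnot(abs(slope) < 1, n >= 3)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  with_seed(seed, {
    x <- rnorm(n)
    y <- slope * x + sqrt(1 - slope^2) * rnorm(n)
    data.frame(x = x * sd_ratio, y = y)
  })
}

# ---- internals ------------------------------------------------------------

draw_constituents <- function(params, n) {
  cn <- names(params$marginal_means)
  R6 <- params$target_correlation[cn, cn]
  S6 <- diag(params$marginal_sds) %*% R6 %*% diag(params$marginal_sds)
  L <- chol(S6 + diag(1e-10, length(cn)))
  X <- matrix(rnorm(n * length(cn)), n) %*% L
  X <- sweep(X, 2, params$marginal_means, "+")
  X[X < 0.05] <- 0.05        # Gaussian-copula clipping at the physical floor
  colnames(X) <- cn
  X
}

in_range_box <- function(X, box) {
  tnc2 <- 100 - rowSums(X[, c("ash", "lignin", "ap", "cellulose",
                              "hemicellulose")])
  total <- X[, "ap"] + X[, "cellulose"] + X[, "hemicellulose"] + tnc2
  x <- 100 * tnc2 / total
  y <- 100 * X[, "ap"] / total
  i <- 100 - x - y
  x >= box["min", "x"] & x <= box["max", "x"] &
    y >= box["min", "y"] & y <= box["max", "y"] &
    i >= box["min", "i"] & i <= box["max", "i"]
}

# Solve the latent-score direction that realizes the requested per-type
# contrasts in lignin and microbial N by upper-tail selection, then assign.
assign_diet_types <- function(X, params) {
  n <- nrow(X)
  probs <- params$diet_type_probs
  eff <- params$diet_effects
  elevated <- "shrub_sugar"
  others <- setdiff(names(probs), elevated)
  p_s <- probs[[elevated]]
  overall <- colSums(eff[match(names(probs), eff$diet_type),
                         c("lignin", "microbial_n")] * probs)
  d <- unlist(eff[eff$diet_type == elevated, c("lignin", "microbial_n")]) -
    overall
  lam <- dnorm(qnorm(1 - p_s)) / p_s     # E[z | upper p_s tail], z ~ N(0,1)
  sds <- params$marginal_sds[c("lignin", "microbial_n")]
  rho_req <- d / (sds * lam)
  r_lm <- params$target_correlation["lignin", "microbial_n"]
  k <- rho_req[1] / rho_req[2]
  b <- (1 - k * r_lm) / (k - r_lm)       # direction with a = 1
  a <- 1
  s <- sqrt(a^2 + b^2 + 2 * a * b * r_lm)
  rho_att <- (a + b * r_lm) / s
  shrinkf <- rho_req[1] / rho_att
  if (shrinkf > 1) {
    warning("requested diet-type contrasts exceed what tail selection can ",
            "realize; using the attainable maximum", call. = FALSE)
    tau <- 0
  } else {
    tau <- s * sqrt(1 / shrinkf^2 - 1)
  }
  z <- a * standardize(X[, "lignin"]) + b * standardize(X[, "microbial_n"]) +
    tau * rnorm(n)
  diet <- rep(NA_character_, n)
  shrub <- z >= quantile(z, 1 - p_s)
  diet[shrub] <- elevated
  diet[!shrub] <- sample(others, sum(!shrub), replace = TRUE,
                         prob = probs[others] / sum(probs[others]))
  diet
}

assign_subpops <- function(diet, subpops, min_per_subpop) {
  mmu <- rep(NA_character_, length(diet))
  for (dt in unique(diet)) {
    units <- subpops$mmu[subpops$diet_type == dt]
    if (!length(units)) units <- subpops$mmu  # no unit of this type: pool
    idx <- sample(which(diet == dt))     # shuffle within type
    if (length(idx) < min_per_subpop * length(units)) {
      warning("too few '", dt, "' samples to give every subpopulation ",
              min_per_subpop, " members", call. = FALSE)
    }
    base <- rep(units, each = min_per_subpop)
    fill <- sample(units, max(0, length(idx) - length(base)), replace = TRUE)
    mmu[idx] <- c(base, fill)[seq_along(idx)]
  }
  mmu
}

draw_metadata <- function(n, subrows, params) {
  cls <- sample(names(params$agesex_probs), n, replace = TRUE,
                prob = params$agesex_probs)
  age_class <- sub("_[fm]$", "", cls)
  sex <- ifelse(grepl("_f$", cls), "f", "m")
  # early window spans the season opening (mid-October) through November,
  # late December through late February; area A inverts the 70:30 split
  p_early <- ifelse(subrows$mma == "A", 1 - params$early_late_split,
                    params$early_late_split)
  early <- runif(n) < p_early
  d0 <- as.Date("2014-10-13")
  date <- as.Date(ifelse(early,
                         d0 + sample(0:48, n, replace = TRUE),
                         as.Date("2014-12-01") + sample(0:83, n, TRUE)),
                  origin = "1970-01-01")
  bm_mean_i <- ifelse(age_class == "calf", params$calf_bm_mean,
                      ifelse(age_class == "yearling", 130,
                             ifelse(sex == "f", 170, 190)))
  bm_sd_i <- ifelse(age_class == "calf", params$calf_bm_sd,
                    ifelse(age_class == "yearling", 15, 22))
  body_mass <- rnorm(n, bm_mean_i + subrows$bm_offset, bm_sd_i)
  data.frame(age_class = age_class, sex = sex, date = date,
             body_mass = round(pmax(body_mass, 20), 1),
             stringsAsFactors = FALSE)
}

# Evaluate code under a seed without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
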