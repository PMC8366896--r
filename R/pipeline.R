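#' Pipeline configuration
#'
#' Collects the end-to-end analysis settings.  Defaults reproduce the
#' study-design filters: subpopulation-level analyses keep only management
#' units with at least 5 samples collected on or after 23 October, while
#' sample-based analyses (RMT, correlation matrix) use every sample.
#'
#' @param input Path to the proximate-record CSV (see
#'   [read_proximate_csv()]), or a data frame of records.
#' @param date_min Earliest date admitted to the restricted analyses
#'   (ISO-8601); NULL disables the filter.
#' @param min_samples_per_mmu Minimum samples per management unit for
#'   subpopulation-level analyses.
#' @param plant_constituents Constituent list for the plant PCA.
#' @param standardized_interaction Fit the diet-type interaction model on
#'   standardized data (default FALSE: raw scale).
#' @param seed Seed recorded in the provenance block and used for any
#'   stochastic stage.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input = NULL,
                            date_min = "2014-10-23",
                            min_samples_per_mmu = 5,
                            plant_constituents = plant_pca_constituents(6),
                            standardized_interaction = FALSE,
                            seed = 1) {
  out <- list(input = input,
              date_min = if (is.null(date_min)) NULL else as.Date(date_min),
              min_samples_per_mmu = min_samples_per_mmu,
              plant_constituents = plant_constituents,
              standardized_interaction = standardized_interaction,
              seed = seed)
  class(out) <- "pipeline_config"
  out
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the [pipeline_config()] arguments.
#' @return A \code{pipeline_config} object.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Validate a proximate-record input file
#'
#' Runs the full record validation without deriving profiles: schema and
#' dialect checks, range checks, detergent-ladder and nitrogen ordering,
#' closure feasibility.  Row numbers refer to data rows of the file
#' (header excluded).
#'
#' @param path CSV path or data frame of records.
#' @param source_kind \code{"rumen"} or \code{"plant"}.
#' @return Validation report data frame (see [validation_report()]) with an
#'   additional \code{row} column; zero rows for a clean file.
#' @export
validate_input <- function(path, source_kind = "rumen") {
  records <- if (is.character(path)) read_proximate_csv(path) else
    as.data.frame(path)
  prof <- suppressWarnings(derive_profiles(records, source_kind))
  rep <- validation_report(prof)
  rep$row <- match(rep$sample_id, records$sample_id)
  rep
}

#' Run the full macronutrient-balance analysis pipeline
#'
#' Derives macronutrient profiles from the input records, projects them into
#' RMT coordinates, and runs the analysis battery: the constituent
#' correlation matrix, age-sex ANOVAs, the standardized isometric-scaling
#' regression of \%AP on \%TNC2+lipids, the balance-ratio versus fiber model
#' (with diet-type interaction when labels are present, plus the
#' quasi-binomial cross-check), and the subpopulation ratio versus calf
#' body-mass regression under the design filters.  Results and a provenance
#' block are written to \code{output_dir} as CSV/JSON when supplied.
#'
#' @param config A [pipeline_config()] object.
#' @param output_dir Optional directory for the report bundle.
#' @return List of class \code{pipeline_report}: \code{profiles},
#'   \code{rmt}, \code{correlations}, \code{anova} (per constituent),
#'   \code{isometry}, \code{ratio_fiber}, \code{ratio_fiber_interaction},
#'   \code{ratio_fiber_quasibinomial}, \code{subpop_bodymass},
#'   \code{observed_range}, \code{validation}, \code{provenance}.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  records <- if (is.character(config$input)) {
    read_proximate_csv(config$input)
  } else if (is.data.frame(config$input)) {
    config$input
  } else stop("config$input must be a CSV path or a data frame",
              call. = FALSE)

  profiles <- suppressWarnings(derive_profiles(records, "rumen"))
  meta_cols <- intersect(c("mma", "mmu", "age_class", "sex", "body_mass",
                           "date", "diet_type"), names(records))
  meta <- records[match(profiles$sample_id, records$sample_id), meta_cols,
                  drop = FALSE]
  samples <- cbind(profiles, meta)
  rmt <- rmt_points(profiles)
  samples$x <- rmt$x; samples$y <- rmt$y; samples$i <- rmt$i
  samples$ratio <- samples$y / samples$x

  const_cols <- c("ash", "lignin", "microbial_n", "ap", "cellulose",
                  "hemicellulose", "tnc2_lipids")
  have <- const_cols[colSums(!is.na(samples[const_cols])) >= 3]
  correlations <- pearson_matrix(samples[, have])

  anovas <- NULL
  if (all(c("age_class", "sex") %in% names(samples))) {
    cls <- interaction(samples$age_class, samples$sex, drop = TRUE)
    if (nlevels(cls) >= 2 && all(table(cls) >= 2)) {
      anovas <- lapply(setNames(have, have), function(cc) {
        v <- samples[[cc]]
        ok <- !is.na(v)
        anova_tukey(v[ok], cls[ok])
      })
    }
  }

  isometry <- isometry_test(samples$y, samples$x, standardize = TRUE)
  ratio_fiber <- ratio_fiber_model(samples$ratio, samples$i)

  interaction_fit <- NULL
  quasi_fit <- NULL
  if ("diet_type" %in% names(samples)) {
    lab <- !is.na(samples$diet_type) & samples$diet_type != ""
    sub <- samples[lab, ]
    if (!is.null(config$date_min)) {
      sub <- sub[!is.na(sub$date) & sub$date >= config$date_min, ]
    }
    if (length(unique(sub$diet_type)) >= 2) {
      interaction_fit <- ratio_fiber_model(
        sub$ratio, sub$i, sub$diet_type,
        standardize = config$standardized_interaction)
      quasi_fit <- ratio_fiber_model(
        sub$ratio, sub$i, sub$diet_type, standardize = FALSE,
        family = "quasibinomial")
    }
  }

  subpop_fit <- NULL
  if (all(c("mmu", "age_class", "body_mass") %in% names(samples))) {
    sub <- samples
    if (!is.null(config$date_min)) {
      sub <- sub[!is.na(sub$date) & sub$date >= config$date_min, ]
    }
    tab <- table(sub$mmu)
    keep_mmu <- names(tab)[tab >= config$min_samples_per_mmu]
    sub <- sub[sub$mmu %in% keep_mmu, ]
    if (length(unique(sub$mmu)) >= 3) {
      calf_bm <- ifelse(sub$age_class == "calf", sub$body_mass, NA_real_)
      subpop_fit <- subpop_ratio_vs_bodymass(data.frame(
        mmu = sub$mmu, ratio = sub$ratio, calf_body_mass = calf_bm))
    }
  }

  report <- list(
    profiles = profiles, rmt = rmt, samples = samples,
    correlations = correlations, anova = anovas,
    isometry = isometry, ratio_fiber = ratio_fiber,
    ratio_fiber_interaction = interaction_fit,
    ratio_fiber_quasibinomial = quasi_fit,
    subpop_bodymass = subpop_fit,
    observed_range = observed_range(rmt),
    validation = validation_report(profiles),
    provenance = list(
      package_version = as.character(packageVersion("rumenbalance")),
      seed = config$seed,
      date_min = as.character(config$date_min),
      min_samples_per_mmu = config$min_samples_per_mmu,
      n_records_in = nrow(records),
      n_records_kept = nrow(profiles),
      config_hash = config_hash(config)))
  class(report) <- "pipeline_report"
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Macronutrient-balance pipeline report\n")
  cat("  samples kept:", nrow(x$profiles), "of",
      x$provenance$n_records_in, "\n")
  cat(sprintf("  isometric scaling: slope %.3f +/- %.3f (R2 = %.2f)\n",
              x$isometry$slope, x$isometry$slope_se, x$isometry$r_squared))
  cat(sprintf("  ratio vs fiber:    slope %.3f +/- %.3f (R2 = %.2f)\n",
              x$ratio_fiber$slope, x$ratio_fiber$slope_se,
              x$ratio_fiber$r_squared))
  if (!is.null(x$subpop_bodymass)) {
    cat(sprintf("  subpop BM vs ratio: t = %.3f, p = %.2f (df = %d)\n",
                x$subpop_bodymass$t_vs_zero, x$subpop_bodymass$p_two_sided,
                as.integer(x$subpop_bodymass$df)))
  }
  invisible(x)
}

write_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(file.path(output_dir, "INCOMPLETE"), force = TRUE))
  file.create(file.path(output_dir, "INCOMPLETE"))
  write.csv(report$profiles, file.path(output_dir, "profiles.csv"),
            row.names = FALSE)
  write.csv(report$rmt, file.path(output_dir, "rmt_points.csv"),
            row.names = FALSE)
  write.csv(report$validation, file.path(output_dir, "validation.csv"),
            row.names = FALSE)
  write.csv(flatten_results(report), file.path(output_dir, "results.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(provenance = report$provenance,
         observed_range = as.data.frame(report$observed_range),
         correlations = report$correlations$r),
    file.path(output_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  file.remove(file.path(output_dir, "INCOMPLETE"))
  ok <- TRUE
  invisible(output_dir)
}

# Flat (term, estimate, se, t, p, df) table across the fitted models.
flatten_results <- function(report) {
  rows <- list()
  add <- function(term, est, se, t, p, df) {
    rows[[length(rows) + 1]] <<- data.frame(
      term = term, estimate = est, se = se, t = t, p = p, df = df)
  }
  iso <- report$isometry
  add("isometry_slope", iso$slope, iso$slope_se, iso$t_vs_zero,
      iso$p_two_sided, iso$df)
  add("isometry_slope_vs_one", iso$slope - 1, iso$slope_se, iso$t_vs_one,
      iso$p_vs_one, iso$df)
  rf <- report$ratio_fiber
  add("ratio_fiber_slope", rf$slope, rf$slope_se, rf$t_vs_zero,
      rf$p_two_sided, rf$df)
  if (!is.null(report$ratio_fiber_interaction)) {
    for (k in seq_len(nrow(report$ratio_fiber_interaction$interaction))) {
      ir <- report$ratio_fiber_interaction$interaction[k, ]
      add(paste0("interaction_", gsub(" ", "_", ir$contrast)), ir$estimate,
          ir$se, ir$t, ir$p, report$ratio_fiber_interaction$df_residual)
    }
  }
  if (!is.null(report$subpop_bodymass)) {
    sb <- report$subpop_bodymass
    add("subpop_bm_vs_ratio", sb$slope, sb$slope_se, sb$t_vs_zero,
        sb$p_two_sided, sb$df)
  }
  do.call(rbind, rows)
}

config_hash <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "input")]),
             collapse = "")
  # small deterministic polynomial hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}
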