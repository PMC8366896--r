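#' Available protein from total and fiber-bound nitrogen
#'
#' Available protein (AP) is total protein minus the protein rendered
#' indigestible by binding to acid-detergent fiber: both nitrogen pools are
#' converted with the standard factor 6.25 (proteins average ca 16% N), so
#' \code{AP = 6.25 * (total_n - adf_n)}.  For rumen samples the same quantity
#' is conventionally written AP_R because the available-nitrogen pool then
#' also contains nitrogen of microbial origin.
#'
#' @param total_n Kjeldahl (total) nitrogen, \% of dry matter.
#' @param adf_n Nitrogen bound in acid-detergent fiber, \% of dry matter.
#' @param sample_id Optional identifiers used in error messages.
#' @return Available protein, \% of dry matter, same length as the inputs.
#' @examples
#' available_protein(1.408, 0.496)  # 5.7 % of dm
#' available_protein(2, 0)          # 12.5: no bound N
#' @export
available_protein <- function(total_n, adf_n, sample_id = NULL) {
  check_numeric(total_n, "total_n")
  check_numeric(adf_n, "adf_n")
  bad <- which(adf_n > total_n | adf_n < 0)
  if (length(bad)) {
    stop("adf_n must satisfy 0 <= adf_n <= total_n; violated for ",
         bad_sample_label(bad, sample_id), call. = FALSE)
  }
  N_TO_PROTEIN * (total_n - adf_n)
}

#' Hemicellulose and cellulose from the detergent-fiber ladder
#'
#' The sequential detergent system partitions cell-wall material as
#' NDF = hemicellulose + cellulose + lignin and ADF = cellulose + lignin,
#' so \code{hemicellulose = ndf - adf} and \code{cellulose = adf - lignin}.
#'
#' @param ndf,adf,lignin Neutral-detergent fiber, acid-detergent fiber and
#'   lignin, all \% of dry matter, with \code{ndf >= adf >= lignin}.
#' @param sample_id Optional identifiers used in error messages.
#' @return A data frame with columns \code{hemicellulose} and
#'   \code{cellulose} (\% of dry matter).
#' @examples
#' fiber_fractions(50, 30, 10)  # hemicellulose 20, cellulose 20
#' @export
fiber_fractions <- function(ndf, adf, lignin, sample_id = NULL) {
  check_numeric(ndf, "ndf"); check_numeric(adf, "adf")
  check_numeric(lignin, "lignin")
  bad <- which(!(ndf >= adf & adf >= lignin & lignin >= 0))
  if (length(bad)) {
    stop("detergent-fiber ordering ndf >= adf >= lignin >= 0 violated for ",
         bad_sample_label(bad, sample_id), call. = FALSE)
  }
  data.frame(hemicellulose = ndf - adf, cellulose = adf - lignin)
}

#' Nonstructural carbohydrates plus lipids by subtraction (rumen)
#'
#' For rumen material the quickly digestible constituents cannot be measured
#' reliably (residence time and digestion state are unknown), so the combined
#' pool is estimated by compositional closure:
#' \code{TNC2 + lipids = 100 - (NDF + AP + ash)}.
#'
#' Small negative results (within \code{tolerance} percentage points, i.e.
#' input rounding) are clipped to zero with a warning; larger deficits raise
#' an error naming the offending samples.
#'
#' @param ndf Neutral-detergent fiber, \% of dry matter.
#' @param ap Available protein, \% of dry matter.
#' @param ash Ash, \% of dry matter.
#' @param tolerance Clipping tolerance in percentage points (default 0.5).
#' @param sample_id Optional identifiers used in messages.
#' @return TNC2+lipids, \% of dry matter.
#' @examples
#' tnc2_lipids(50, 20, 5)  # 25
#' @export
tnc2_lipids <- function(ndf, ap, ash, tolerance = 0.5, sample_id = NULL) {
  check_numeric(ndf, "ndf"); check_numeric(ap, "ap"); check_numeric(ash, "ash")
  out <- 100 - (ndf + ap + ash)
  bad <- which(out < -tolerance)
  if (length(bad)) {
    stop("ndf + ap + ash exceeds 100 beyond tolerance (", tolerance,
         ") for ", bad_sample_label(bad, sample_id), call. = FALSE)
  }
  clip <- which(out < 0)
  if (length(clip)) {
    warning("TNC2+lipids clipped to 0 within tolerance for ",
            bad_sample_label(clip, sample_id), call. = FALSE)
    out[clip] <- 0
  }
  out
}

#' Nonstructural carbohydrates measured enzymatically (plants)
#'
#' For plant material, water-soluble carbohydrates (sugars) and starch are
#' measured enzymatically and summed: \code{TNC1 = sugars + starch}.
#'
#' @param sugars,starch \% of dry matter, both non-negative.
#' @return TNC1, \% of dry matter.
#' @export
tnc1 <- function(sugars, starch) {
  check_numeric(sugars, "sugars"); check_numeric(starch, "starch")
  if (any(sugars < 0 | starch < 0)) {
    stop("sugars and starch must be non-negative", call. = FALSE)
  }
  sugars + starch
}

#' Microbial nitrogen from the purine marker
#'
#' Total purines (measured against a yeast-RNA standard, in g yeast-RNA
#' equivalents per 100 g dry matter) are converted to nitrogen of microbial
#' origin with the empirical factor 1.1.
#'
#' @param purine_marker g yeast-RNA equivalents / 100 g dry matter.
#' @return Microbial N, \% of dry matter.
#' @examples
#' microbial_n(1)  # 1.1
#' @export
microbial_n <- function(purine_marker) {
  check_numeric(purine_marker, "purine_marker")
  if (any(purine_marker < 0, na.rm = TRUE)) {
    stop("purine_marker must be non-negative", call. = FALSE)
  }
  PURINE_TO_MICROBIAL_N * purine_marker
}

#' Derive macronutrient profiles from proximate records
#'
#' Applies the full derivation ladder to a table of proximate-analysis
#' records: crude protein (6.25 x total N), available protein, hemicellulose
#' and cellulose from the detergent ladder, and either the subtraction
#' estimate TNC2+lipids (rumen) or the enzymatic TNC1 = sugars + starch
#' (plants).  Rumen profiles satisfy the closure identity
#' \code{ap + ndf + ash + tnc2_lipids = 100} exactly, which expands to
#' \code{ap + cellulose + hemicellulose + lignin + ash + tnc2_lipids = 100}.
#'
#' Records violating a validation rule beyond tolerance are dropped; the
#' returned data frame carries a \code{"validation"} attribute listing every
#' rejected or clipped record with the reason.
#'
#' @param records Data frame with columns \code{sample_id}, \code{ash},
#'   \code{total_n}, \code{adf_n}, \code{ndf}, \code{adf}, \code{lignin} and,
#'   depending on \code{source_kind}, \code{purine_marker} (rumen, optional)
#'   or \code{sugars}, \code{starch}, \code{lipids} (plants).  All
#'   compositional columns are \% of dry matter.
#' @param source_kind \code{"rumen"} or \code{"plant"}.
#' @param tolerance Clipping tolerance passed to [tnc2_lipids()] and used for
#'   small negative derived values (default 0.5 percentage points).
#' @return Data frame of macronutrient profiles, one row per accepted record:
#'   \code{sample_id}, \code{crude_protein}, \code{ap}, \code{cellulose},
#'   \code{hemicellulose}, \code{fiber}, \code{lignin}, \code{ash}, and
#'   \code{tnc2_lipids} + \code{microbial_n} (rumen) or \code{tnc1} +
#'   \code{lipids} (plant); plus a \code{source_kind} column.  Attribute
#'   \code{"validation"} holds the validation report (see
#'   [validation_report()]).
#' @export
derive_profiles <- function(records, source_kind = c("rumen", "plant"),
                            tolerance = 0.5) {
  source_kind <- match.arg(source_kind)
  records <- as.data.frame(records)
  needed <- c("sample_id", "ash", "total_n", "adf_n", "ndf", "adf", "lignin")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("records is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  issues <- data.frame(sample_id = character(), rule = character(),
                       action = character(), detail = character(),
                       stringsAsFactors = FALSE)
  note <- function(ids, rule, action, detail) {
    if (!length(ids)) return()
    issues <<- rbind(issues, data.frame(
      sample_id = as.character(ids), rule = rule, action = action,
      detail = detail, stringsAsFactors = FALSE))
  }

  keep <- rep(TRUE, nrow(records))
  with_rec <- function(expr) eval(expr, records, parent.frame())

  frac_cols <- intersect(c("ash", "total_n", "adf_n", "ndf", "adf", "lignin",
                           "lipids", "sugars", "starch"), names(records))
  for (cc in frac_cols) {
    v <- records[[cc]]
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(bad)) {
      note(records$sample_id[bad], paste0(cc, " outside [0, 100]"),
           "rejected", paste0(cc, " = ", signif(v[bad], 4)))
      keep[bad] <- FALSE
    }
  }
  bad <- with_rec(quote(which(!(ndf >= adf & adf >= lignin & lignin >= 0))))
  note(records$sample_id[bad], "ndf >= adf >= lignin >= 0 violated",
       "rejected", with_rec(quote(paste0("ndf=", ndf, " adf=", adf,
                                         " lignin=", lignin)))[bad])
  keep[bad] <- FALSE
  bad <- with_rec(quote(which(!(total_n >= adf_n & adf_n >= 0))))
  note(records$sample_id[bad], "total_n >= adf_n >= 0 violated", "rejected",
       with_rec(quote(paste0("total_n=", total_n, " adf_n=", adf_n)))[bad])
  keep[bad] <- FALSE

  r <- records[keep, , drop = FALSE]
  ap <- available_protein(r$total_n, r$adf_n, r$sample_id)
  ff <- fiber_fractions(r$ndf, r$adf, r$lignin, r$sample_id)
  out <- data.frame(
    sample_id = r$sample_id,
    crude_protein = N_TO_PROTEIN * r$total_n,
    ap = ap,
    cellulose = ff$cellulose,
    hemicellulose = ff$hemicellulose,
    fiber = ff$cellulose + ff$hemicellulose,
    lignin = r$lignin,
    ash = r$ash,
    source_kind = source_kind,
    stringsAsFactors = FALSE)

  if (source_kind == "rumen") {
    over <- which(100 - (r$ndf + ap + r$ash) < -tolerance)
    if (length(over)) {
      note(r$sample_id[over], "ndf + ap + ash > 100 beyond tolerance",
           "rejected",
           paste0("sum = ", signif((r$ndf + ap + r$ash)[over], 5)))
      r <- r[-over, , drop = FALSE]
      out <- out[-over, , drop = FALSE]
      ap <- ap[-over]
    }
    tl <- 100 - (r$ndf + ap + r$ash)
    clip <- which(tl < 0)
    if (length(clip)) {
      note(r$sample_id[clip], "TNC2+lipids negative within tolerance",
           "clipped to 0", paste0("raw = ", signif(tl[clip], 4)))
      tl[clip] <- 0
    }
    out$tnc2_lipids <- tl
    out$microbial_n <- if ("purine_marker" %in% names(r)) {
      microbial_n(r$purine_marker)
    } else NA_real_
  } else {
    sug <- if ("sugars" %in% names(r)) r$sugars else 0
    sta <- if ("starch" %in% names(r)) r$starch else 0
    out$tnc1 <- tnc1(sug, sta)
    out$lipids <- if ("lipids" %in% names(r)) r$lipids else NA_real_
  }
  if (nrow(issues)) {
    warning(sum(issues$action == "rejected"), " record(s) rejected, ",
            sum(issues$action != "rejected"),
            " clipped during profile derivation", call. = FALSE)
  }
  attr(out, "validation") <- issues
  out
}

#' Validation report of a derivation
#'
#' @param profiles Result of [derive_profiles()] or [validate_input()].
#' @return Data frame with columns \code{sample_id}, \code{rule},
#'   \code{action}, \code{detail}; zero rows when everything passed.
#' @export
validation_report <- function(profiles) {
  rep <- attr(profiles, "validation")
  if (is.null(rep)) {
    rep <- data.frame(sample_id = character(), rule = character(),
                      action = character(), detail = character(),
                      stringsAsFactors = FALSE)
  }
  rep
}

#' Read a proximate-analysis CSV
#'
#' Expects UTF-8, comma-separated, decimal point, header row with the
#' canonical column names (\code{sample_id}, chemistry columns, and optional
#' metadata \code{mma}, \code{mmu}, \code{age_class}, \code{sex},
#' \code{body_mass}, \code{date}, \code{diet_type}).  A file whose numeric
#' columns contain decimal commas is rejected outright rather than silently
#' misparsed.
#'
#' @param path Path to the CSV file.
#' @return Data frame of raw records (no validation applied; see
#'   [validate_input()] and [derive_profiles()]).
#' @export
read_proximate_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("input CSV must have a sample_id column", call. = FALSE)
  }
  num_cols <- intersect(
    c("ash", "total_n", "adf_n", "ndf", "adf", "lignin", "lipids", "sugars",
      "starch", "purine_marker", "body_mass"), names(df))
  for (cc in num_cols) {
    v <- df[[cc]]
    if (is.character(v)) {
      if (any(grepl(",", v, fixed = TRUE))) {
        stop("column '", cc, "' contains decimal commas; ",
             "inputs must use the point decimal separator", call. = FALSE)
      }
      df[[cc]] <- as.numeric(v)
    }
  }
  if ("date" %in% names(df)) df$date <- as.Date(df$date)
  df
}

check_numeric <- function(x, name) {
  if (!is.numeric(x)) stop(name, " must be numeric", call. = FALSE)
  invisible(x)
}

bad_sample_label <- function(idx, sample_id) {
  if (is.null(sample_id)) {
    paste0("element(s) ", paste(idx, collapse = ", "))
  } else {
    paste0("sample(s) ", paste(sample_id[idx], collapse = ", "))
  }
}
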