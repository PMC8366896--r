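#' Winter nutritional composition of 12 common moose food plants
#'
#' Packaged reference table of the mean winter composition (\% of dry
#' matter, one decimal) of twelve woody plants and dwarf shrubs that
#' together dominate the winter diet of moose in southern Sweden: crude
#' protein, available protein, enzymatically determined nonstructural
#' carbohydrates (TNC1), lipids, lignin, cellulose, hemicellulose, NDF and
#' the in vitro digestible fraction of NDF (dNDF).  Values are stored
#' verbatim as printed in the source table; the fiber sub-fractions do not
#' always re-add exactly to the printed NDF (up to ~3 percentage points),
#' and no reconciliation is attempted.
#'
#' @return Data frame with one row per species.
#' @export
moose_plants <- function() {
  path <- system.file("extdata", "moose_food_plants.csv",
                      package = "rumenbalance", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Composition of five common supplementary feeds (partly synthetic)
#'
#' Available protein, NDF and TNC for the five supplementary foods commonly
#' offered to game in southern Sweden (three root vegetables, peas, and
#' grass silage).  Only the TNC anchors of the root crops are published
#' alongside the plant table (74\% starch in \emph{Solanum tuberosum}, 65\%
#' sugar in \emph{Beta vulgaris}, 60\% sugar in \emph{Daucus carota}); the
#' remaining entries are synthetic stand-ins at feed-table magnitudes, kept
#' in a clearly marked fixture so they can be overridden with real values.
#'
#' @param path Optional CSV with columns \code{feed}, \code{ap}, \code{ndf},
#'   \code{tnc1} overriding the packaged synthetic fixture.
#' @return Data frame with one row per feed.
#' @export
supplementary_feeds <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "supplementary_feeds_synthetic.csv",
                        package = "rumenbalance", mustWork = TRUE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("feed", "ap", "ndf", "tnc1")
  gaps <- setdiff(need, names(df))
  if (length(gaps)) {
    stop("feed table is missing: ", paste(gaps, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df[, c("ap", "ndf", "tnc1")])) {
    bad <- df$feed[!complete.cases(df[, c("ap", "ndf", "tnc1")])]
    stop("feed table has missing values for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Pairwise correlations among plant nutritional constituents
#'
#' Pearson correlation matrix (with two-sided p-values) of six constituents
#' -- lignin, cellulose, hemicellulose, available protein, TNC1 and lipids --
#' across the twelve packaged food plants.  Shares the [pearson_matrix()]
#' code path used for rumen constituents.
#'
#' @param plants Plant table; defaults to the packaged [moose_plants()].
#' @return A \code{pearson_matrix} object (6 x 6).
#' @export
plant_correlations <- function(plants = moose_plants()) {
  cols <- c("lignin", "cellulose", "hemicellulose", "ap", "tnc1", "lipids")
  pearson_matrix(plants[, cols])
}

#' PCA of plant nutritional composition
#'
#' Principal component analysis of the standardized (correlation-matrix)
#' composition of the twelve packaged food plants.  The default constituent
#' set is the six variables shown in the published loading plot (lignin,
#' cellulose, hemicellulose, available protein, TNC1, dNDF); passing
#' \code{constituents = plant_pca_constituents(7)} adds lipids for the
#' seven-variable variant.  Loadings follow a deterministic sign convention:
#' within each component the entry with the largest absolute loading is made
#' positive.
#'
#' @param constituents Character vector of column names in the plant table.
#' @param plants Plant table; defaults to [moose_plants()].
#' @return Object of class \code{foodscape_pca}: \code{loadings},
#'   \code{scores}, \code{variance_explained} (fractions summing to 1),
#'   \code{constituents}.
#' @export
plant_pca <- function(constituents = plant_pca_constituents(6),
                      plants = moose_plants()) {
  unknown <- setdiff(constituents, names(plants))
  if (length(unknown)) {
    stop("unknown constituent(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  run_pca(plants[, constituents, drop = FALSE], plants$species)
}

#' Default constituent sets for the plant PCA
#'
#' @param n 6 (published loading plot: lignin, cellulose, hemicellulose,
#'   available protein, TNC1, dNDF) or 7 (adds lipids).
#' @return Character vector of column names.
#' @export
plant_pca_constituents <- function(n = 6) {
  base <- c("lignin", "cellulose", "hemicellulose", "ap", "tnc1", "dndf")
  if (n == 6) base else if (n == 7) c(base, "lipids") else
    stop("n must be 6 or 7", call. = FALSE)
}

#' Joint PCA of food plants and supplementary feeds
#'
#' PCA (standardized columns) of the twelve plants plus the five
#' supplementary feeds on the three constituents available for both:
#' available protein, NDF and TNC.
#'
#' @param feed_table Feed composition table; defaults to
#'   [supplementary_feeds()] (partly synthetic, see its help page).
#' @param plants Plant table; defaults to [moose_plants()].
#' @return A \code{foodscape_pca} object over the 17 items, with an
#'   \code{item_kind} column ("plant"/"feed") attached to the scores.
#' @export
feed_comparison_pca <- function(feed_table = supplementary_feeds(),
                                plants = moose_plants()) {
  cols <- c("ap", "ndf", "tnc1")
  items <- rbind(
    data.frame(item = plants$species, plants[, cols], kind = "plant",
               stringsAsFactors = FALSE),
    data.frame(item = feed_table$feed, feed_table[, cols], kind = "feed",
               stringsAsFactors = FALSE))
  out <- run_pca(items[, cols], items$item)
  out$item_kind <- items$kind
  out
}

#' Convex nutritional space spanned by the food plants
#'
#' Projects the plant table into RMT coordinates (available protein vs
#' TNC1+lipids vs cellulose+hemicellulose, \% of macronutrient total) and
#' returns the convex hull: the nutritional space reachable by a browser
#' mixing those plants.
#'
#' @param plants Plant table or a subset of its rows; defaults to all 12.
#' @return A list with \code{points} (RMT coordinates per species) and
#'   \code{space} (a [nutritional_space()] object).
#' @export
plant_nutritional_space <- function(plants = moose_plants()) {
  prof <- data.frame(sample_id = plants$species, ap = plants$ap,
                     fiber = plants$cellulose + plants$hemicellulose,
                     tnc1 = plants$tnc1, lipids = plants$lipids)
  pts <- rmt_points(prof)
  list(points = pts, space = nutritional_space(pts))
}

run_pca <- function(df, item_names) {
  df <- as.data.frame(df)
  if (ncol(df) == 1) {
    # degenerate one-variable case: a single component carries everything
    loadings <- matrix(1, 1, 1, dimnames = list(names(df), "PC1"))
    scores <- matrix(standardize(df[[1]]), ncol = 1,
                     dimnames = list(item_names, "PC1"))
    out <- list(loadings = loadings, scores = scores,
                variance_explained = 1, constituents = names(df))
    class(out) <- "foodscape_pca"
    return(out)
  }
  pc <- prcomp(df, center = TRUE, scale. = TRUE)
  rot <- pc$rotation
  scores <- pc$x
  for (k in seq_len(ncol(rot))) {      # deterministic sign convention
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) {
      rot[, k] <- -rot[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- item_names
  out <- list(loadings = rot, scores = scores,
              variance_explained = pc$sdev^2 / sum(pc$sdev^2),
              constituents = names(df))
  class(out) <- "foodscape_pca"
  out
}

#' @export
print.foodscape_pca <- function(x, ...) {
  ve <- round(100 * x$variance_explained, 1)
  cat("PCA of", length(x$constituents), "constituents,",
      nrow(x$scores), "items\n")
  cat("Variance explained (%):", paste(ve, collapse = ", "),
      "| PC1+PC2:", round(sum(ve[1:min(2, length(ve))]), 1), "%\n")
  invisible(x)
}
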