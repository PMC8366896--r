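#' Project macronutrient profiles into right-angle mixture triangle (RMT)
#' coordinates
#'
#' An RMT represents a three-component mixture as a two-dimensional Cartesian
#' point: the x-axis carries the proportion of highly digestible
#' macronutrients (TNC2+lipids for rumen material, TNC1+lipids for plants),
#' the y-axis available protein, and the third component -- fiber, i.e.
#' cellulose + hemicellulose -- is implicit as \code{i = 100 - x - y}.
#' Each component is expressed as a percentage of the macronutrient total
#' (ap + fiber + tnc); lignin and ash are excluded from the denominator.
#'
#' @param profiles Data frame from [derive_profiles()], or any data frame
#'   with columns \code{ap}, \code{fiber} (or \code{cellulose} +
#'   \code{hemicellulose}) and either \code{tnc2_lipids} or \code{tnc1} (+
#'   optional \code{lipids}).
#' @param floor Smallest admissible macronutrient total; profiles whose
#'   ap + fiber + tnc falls below it are rejected as degenerate.
#' @return Data frame with columns \code{sample_id} (if present), \code{x},
#'   \code{y}, \code{i} and \code{source_kind}; rows sum to 100.
#' @examples
#' rmt_points(data.frame(ap = 25, fiber = 30, tnc2_lipids = 45))
#' @export
rmt_points <- function(profiles, floor = 1e-6) {
  profiles <- as.data.frame(profiles)
  if (!"fiber" %in% names(profiles)) {
    if (all(c("cellulose", "hemicellulose") %in% names(profiles))) {
      profiles$fiber <- profiles$cellulose + profiles$hemicellulose
    } else {
      stop("profiles need a fiber column (or cellulose + hemicellulose)",
           call. = FALSE)
    }
  }
  if ("tnc2_lipids" %in% names(profiles)) {
    tnc <- profiles$tnc2_lipids
    kind <- "rumen"
  } else if ("tnc1" %in% names(profiles)) {
    tnc <- profiles$tnc1
    if ("lipids" %in% names(profiles)) {
      tnc <- tnc + ifelse(is.na(profiles$lipids), 0, profiles$lipids)
    }
    kind <- "plant"
  } else {
    stop("profiles need tnc2_lipids (rumen) or tnc1 (plant)", call. = FALSE)
  }
  total <- profiles$ap + profiles$fiber + tnc
  if (any(total < floor)) {
    stop("zero (or near-zero) macronutrient total for ",
         bad_sample_label(which(total < floor), profiles$sample_id),
         call. = FALSE)
  }
  out <- data.frame(x = 100 * tnc / total,
                    y = 100 * profiles$ap / total,
                    i = 100 * profiles$fiber / total,
                    source_kind = kind,
                    stringsAsFactors = FALSE)
  if ("sample_id" %in% names(profiles)) {
    out <- cbind(sample_id = profiles$sample_id, out)
  }
  out
}

#' Protein to nonprotein-energy balance ratio
#'
#' The ratio between available protein (y-axis) and the macronutrients
#' providing highly digestible energy (x-axis) of an RMT point:
#' \code{y / x}.
#'
#' @param points Data frame with columns \code{x} and \code{y} (see
#'   [rmt_points()]).
#' @return Numeric vector of ratios.
#' @export
balance_ratio <- function(points) {
  points <- as.data.frame(points)
  if (any(points$x <= 0)) {
    stop("balance ratio undefined where x = 0", call. = FALSE)
  }
  points$y / points$x
}

#' Observed per-axis range of RMT points
#'
#' @param points Data frame with columns \code{x}, \code{y}, \code{i}.
#' @return Matrix with rows \code{min}, \code{max} and columns \code{x},
#'   \code{y}, \code{i}.
#' @export
observed_range <- function(points) {
  points <- as.data.frame(points)
  if (!nrow(points)) stop("no points supplied", call. = FALSE)
  vapply(points[, c("x", "y", "i")],
         function(v) c(min = min(v), max = max(v)), numeric(2))
}

#' Convex nutritional space of a point cloud
#'
#' The nutritional space reachable by mixing the supplied items is the convex
#' hull of their RMT coordinates in the (x, y) plane.  Vertices are returned
#' counter-clockwise starting from the lexicographically smallest vertex, and
#' the area is computed with the shoelace formula (squared-percent units).
#' Fewer than three distinct, non-collinear points yield a degenerate space
#' with area 0 rather than an error.
#'
#' @param points Data frame with columns \code{x} and \code{y}.
#' @return Object of class \code{nutritional_space}: list with
#'   \code{vertices} (data frame \code{x}, \code{y}), \code{area}, and
#'   \code{n_points}.
#' @examples
#' sp <- nutritional_space(data.frame(x = c(0, 10, 0), y = c(0, 0, 10)))
#' sp$area  # 50
#' @export
nutritional_space <- function(points) {
  points <- as.data.frame(points)
  xy <- unique(points[, c("x", "y")])
  degenerate <- nrow(xy) < 3 || all(abs(
    (xy$x - xy$x[1]) * (xy$y[2] - xy$y[1]) -
      (xy$y - xy$y[1]) * (xy$x[2] - xy$x[1])) < 1e-12)
  if (degenerate) {
    verts <- xy[order(xy$x, xy$y), , drop = FALSE]
    rownames(verts) <- NULL
    out <- list(vertices = verts, area = 0, n_points = nrow(points))
    class(out) <- "nutritional_space"
    return(out)
  }
  h <- chull(xy$x, xy$y)           # clockwise order
  verts <- xy[rev(h), , drop = FALSE]  # counter-clockwise
  # rotate so the lexicographically smallest vertex comes first
  lex <- with(verts, order(x, y))[1]
  idx <- c(lex:nrow(verts), seq_len(lex - 1))[seq_len(nrow(verts))]
  verts <- verts[idx, , drop = FALSE]
  rownames(verts) <- NULL
  out <- list(vertices = verts, area = shoelace_area(verts$x, verts$y),
              n_points = nrow(points))
  class(out) <- "nutritional_space"
  out
}

#' @export
print.nutritional_space <- function(x, ...) {
  cat("Nutritional space:", nrow(x$vertices), "hull vertices from",
      x$n_points, "points; area", format(x$area, digits = 6),
      "(squared-% units)\n")
  invisible(x)
}

#' Test whether points lie inside a nutritional space
#'
#' @param space A [nutritional_space()] object.
#' @param points Data frame with columns \code{x}, \code{y}.
#' @param tol Boundary tolerance.
#' @return Logical vector, TRUE for points inside or on the hull boundary.
#' @export
in_space <- function(space, points, tol = 1e-9) {
  stopifnot(inherits(space, "nutritional_space"))
  points <- as.data.frame(points)
  v <- space$vertices
  n <- nrow(v)
  if (n < 3) {
    return(rep(FALSE, nrow(points)))
  }
  inside <- rep(TRUE, nrow(points))
  for (k in seq_len(n)) {
    a <- v[k, ]; b <- v[if (k == n) 1 else k + 1, ]
    # CCW hull: interior points have non-negative cross product for each edge
    cr <- (b$x - a$x) * (points$y - a$y) - (b$y - a$y) * (points$x - a$x)
    inside <- inside & (cr >= -tol)
  }
  inside
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}
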