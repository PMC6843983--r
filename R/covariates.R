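#' The eight-level land-use vocabulary
#'
#' First level (`other`, which pools urban, beaches, sand, bare rock, burnt
#' areas and water bodies) is the reference category of the regression.
#'
#' @return character vector of the 8 category names, reference first.
#' @export
landuse_levels <- function() {
  c("other", "coniferous_forest", "dense_forest", "fruit_trees",
    "artificial_vegetated", "transitional_scrub", "natural_grassland",
    "mixed_forest")
}

#' Default 22-to-8 land-use recode mapping
#'
#' A documented default mapping from 22 raw cover-map codes to the 8 analysis
#' categories.  Real deployments supply their own mapping file (see
#' [read_landuse_mapping()]); this default exists so the pipeline runs end to
#' end on synthetic inputs.
#'
#' @return named character vector: names are raw codes "1".."22", values are
#'   entries of [landuse_levels()].
#' @export
default_landuse_mapping <- function() {
  c("1" = "other", "2" = "other", "3" = "other", "4" = "other",
    "5" = "other", "6" = "other",
    "7" = "coniferous_forest", "8" = "coniferous_forest",
    "9" = "dense_forest", "10" = "dense_forest", "11" = "dense_forest",
    "12" = "fruit_trees", "13" = "fruit_trees",
    "14" = "artificial_vegetated", "15" = "artificial_vegetated",
    "16" = "transitional_scrub", "17" = "transitional_scrub",
    "18" = "natural_grassland", "19" = "natural_grassland",
    "20" = "mixed_forest", "21" = "mixed_forest", "22" = "mixed_forest")
}

#' Recode raw land-use codes to the 8-level vocabulary
#'
#' @param raw_code vector of raw codes (coerced to character).
#' @param mapping named vector raw code -> category name; defaults to
#'   [default_landuse_mapping()].
#' @return factor with levels [landuse_levels()].
#' @export
recode_landuse <- function(raw_code, mapping = default_landuse_mapping()) {
  raw <- as.character(raw_code)
  bad_target <- setdiff(unique(unname(mapping)), landuse_levels())
  if (length(bad_target))
    stop("recode_landuse: mapping targets outside the 8-level vocabulary: ",
         paste(bad_target, collapse = ", "), call. = FALSE)
  unmapped <- setdiff(unique(raw), names(mapping))
  if (length(unmapped))
    stop("recode_landuse: unmapped land-use code(s): ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  factor(unname(mapping[raw]), levels = landuse_levels())
}

#' Categorise a numeric variable by empirical quantiles
#'
#' Cut points are the empirical `k`-quantiles; intervals are left-open /
#' right-closed except the first, which includes the minimum, so boundary
#' ties fall in the lower category.  Category 1 is the reference.
#'
#' @param values numeric vector without NAs.
#' @param k number of groups (`k = 5` for quintiles, `4` for quartiles).
#' @param variable optional variable name stored in the scheme.
#' @return list with `category` (integer in 1..k) and `scheme` (class
#'   `categorization_scheme`: variable, k, boundaries of length k+1).
#' @export
quantile_categorize <- function(values, k = 5L, variable = NULL) {
  if (anyNA(values)) stop("quantile_categorize: NA values not allowed", call. = FALSE)
  if (k < 2) stop("quantile_categorize: k must be >= 2", call. = FALSE)
  if (length(unique(values)) < k)
    stop("quantile_categorize: fewer than k distinct values (degenerate input)", call. = FALSE)
  br <- unname(stats::quantile(values, probs = seq(0, 1, length.out = k + 1), type = 7))
  if (any(diff(br) <= 0))
    stop("quantile_categorize: tied quantile boundaries (degenerate input)", call. = FALSE)
  scheme <- structure(list(variable = variable, k = as.integer(k), boundaries = br),
                      class = "categorization_scheme")
  list(category = apply_scheme(values, scheme), scheme = scheme)
}

#' Apply a stored categorisation scheme to (possibly new) values
#'
#' Values beyond the stored range are clamped into the end categories.
#'
#' @param values numeric vector.
#' @param scheme a `categorization_scheme`.
#' @return integer categories in 1..k.
#' @export
apply_scheme <- function(values, scheme) {
  stopifnot(inherits(scheme, "categorization_scheme"))
  br <- scheme$boundaries
  cat <- cut(values, breaks = br, labels = FALSE, right = TRUE, include.lowest = TRUE)
  cat[values <= br[1]] <- 1L
  cat[values > br[length(br)]] <- scheme$k
  as.integer(cat)
}

#' Default design schemes for the lattice covariates
#'
#' Quintiles for slope, hillshade, elevation and the three proximity
#' distances; quartiles for aspect; the 8-level land-use factor; any
#' `temp_var_*` columns present on the cells enter as continuous covariates.
#'
#' @return list of scheme descriptors consumed by [build_design()].
#' @export
default_design_schemes <- function() {
  c(
    lapply(c("slope", "hillshade", "elevation",
             "dist_urban", "dist_road", "dist_rail"),
           function(v) list(variable = v, type = "quantile", k = 5L)),
    list(list(variable = "aspect", type = "quantile", k = 4L),
         list(variable = "landuse8", type = "categorical",
              levels = landuse_levels()))
  )
}

#' Build the regression design matrix from lattice cells
#'
#' Produces an intercept column plus one indicator per non-reference category
#' per categorised variable (reference = category 1 / first level) plus any
#' continuous covariates, so the column count is
#' \eqn{1 + \sum_v (k_v - 1) + n_{continuous}}.
#'
#' @param cells data.frame of lattice cells (see [generate_lattice()] for the
#'   column contract).
#' @param schemes list of scheme descriptors; each is a list with `variable`,
#'   `type` in `"quantile"`, `"categorical"`, `"continuous"` and, for
#'   quantile schemes, `k` (or a fitted `categorization_scheme` under
#'   `$fitted` to reuse stored boundaries).
#' @return list with `X` (numeric matrix, labelled columns), `labels`
#'   (data.frame column / variable / category), and `schemes` with fitted
#'   boundaries filled in (so the design can be rebuilt on new cells).
#' @export
build_design <- function(cells, schemes = default_design_schemes()) {
  n <- nrow(cells)
  cols <- list(`(Intercept)` = rep(1, n))
  labels <- data.frame(column = "(Intercept)", variable = "(Intercept)",
                       category = NA_character_, stringsAsFactors = FALSE)
  for (si in seq_along(schemes)) {
    sc <- schemes[[si]]
    v <- sc$variable
    if (!v %in% names(cells))
      stop("build_design: variable `", v, "` not found in cells", call. = FALSE)
    vals <- cells[[v]]
    if (sc$type == "quantile") {
      if (!is.null(sc$fitted)) {
        cat <- apply_scheme(vals, sc$fitted)
        fitted <- sc$fitted
      } else {
        qc <- quantile_categorize(vals, k = sc$k, variable = v)
        cat <- qc$category
        fitted <- qc$scheme
      }
      schemes[[si]]$fitted <- fitted
      for (g in 2:fitted$k) {
        nm <- paste0(v, ":Q", g)
        cols[[nm]] <- as.numeric(cat == g)
        labels <- rbind(labels, data.frame(column = nm, variable = v,
                                           category = paste0("Q", g)))
      }
    } else if (sc$type == "categorical") {
      lev <- sc$levels
      f <- if (is.factor(vals)) factor(vals, levels = lev) else factor(as.character(vals), levels = lev)
      if (anyNA(f))
        stop("build_design: values of `", v, "` outside declared levels", call. = FALSE)
      for (g in lev[-1]) {
        nm <- paste0(v, ":", g)
        cols[[nm]] <- as.numeric(f == g)
        labels <- rbind(labels, data.frame(column = nm, variable = v, category = g))
      }
    } else if (sc$type == "continuous") {
      if (anyNA(vals)) stop("build_design: NA in continuous covariate `", v, "`", call. = FALSE)
      cols[[v]] <- as.numeric(vals)
      labels <- rbind(labels, data.frame(column = v, variable = v, category = NA_character_))
    } else stop("build_design: unknown scheme type `", sc$type, "`", call. = FALSE)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  rownames(X) <- NULL
  list(X = X, labels = labels, schemes = schemes)
}
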