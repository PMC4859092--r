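#' Train a self-organizing map on centralized PSF profiles
#'
#' Online Kohonen training of a rectangular grid of meta-PSF weight vectors.
#' Each grid unit holds a prototype profile of length `n_samples`; sinks with
#' similar centralized PSF profiles end up assigned (by Euclidean
#' best-matching unit) to the same or neighboring units, forming the
#' micro-clusters ("meta-PSFs") that the portraits display.
#'
#' Training schedule: unit weights are initialized by a linear blend of
#' observed profiles — the four profiles with extreme combined scores on the
#' first two principal components anchor the grid corners and every unit is
#' their bilinear interpolation, keeping all prototypes inside the convex
#' hull of the data and topologically ordered from the start. In each of
#' `epochs` passes the sinks are presented in
#' a seeded shuffled order; the learning rate decays as
#' `alpha(t) = learning_rate / (1 + lr_constant * t)` with `t` the (0-based)
#' presentation counter, and updates are weighted by a Gaussian neighborhood
#' `exp(-d^2 / (2 * radius^2))` of grid distance `d` around the best-matching
#' unit. Defaults follow the portraying configuration used for pathway
#' activity landscapes: 50 x 50 grid, learning rate 0.02, inverse-learning-rate
#' constant 0.01, neighborhood radius 3, 12 epochs.
#'
#' @param x Sink x sample matrix (rows are the profiles being mapped), e.g.
#'   from [centralize_psf()]. Must be finite with at least 2 rows and 2
#'   columns.
#' @param grid_rows,grid_cols Grid dimensions (default 50 x 50; tests and
#'   desk-scale runs typically use 10 x 10).
#' @param learning_rate Initial learning rate `alpha0` (default 0.02).
#' @param lr_constant Constant `c` in the inverse learning rate
#'   `alpha0 / (1 + c t)` (default 0.01).
#' @param radius Gaussian neighborhood radius in grid units (default 3).
#' @param epochs Number of passes over the data (default 12).
#' @param seed RNG seed controlling initialization and presentation order.
#' @return An object of class `SOMModel`: list with `weights`
#'   (n_units x n_samples matrix, units in row-major grid order), `grid`
#'   (data frame `unit`, `row`, `col`), `assignment` (named integer vector,
#'   sink id -> unit index), and `config`.
#' @export
train_som <- function(x, grid_rows = 50, grid_cols = 50,
                      learning_rate = 0.02, lr_constant = 0.01,
                      radius = 3, epochs = 12, seed = 1) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need at least 2 sinks and 2 samples")
  if (any(!is.finite(x))) stop("non-finite values in SOM input")
  n_units <- grid_rows * grid_cols
  grid <- data.frame(unit = seq_len(n_units),
                     row = rep(seq_len(grid_rows), each = grid_cols),
                     col = rep(seq_len(grid_cols), times = grid_rows))
  # squared grid distances between all unit pairs (small grids only)
  d2 <- outer(grid$row, grid$row, "-")^2 + outer(grid$col, grid$col, "-")^2
  nb <- exp(-d2 / (2 * radius^2))

  weights <- with_seed(seed, {
    W <- som_linear_init(x, grid)
    orders <- lapply(seq_len(epochs), function(e) sample.int(nrow(x)))
    list(W = W, orders = orders)
  })
  W <- weights$W
  t_step <- 0
  for (ep in seq_len(epochs)) {
    for (i in weights$orders[[ep]]) {
      xi <- x[i, ]
      diff <- sweep(W, 2, xi)                       # W - x_i
      bmu <- which.min(rowSums(diff * diff))        # first index on ties
      alpha <- learning_rate / (1 + lr_constant * t_step)
      W <- W - (alpha * nb[, bmu]) * diff
      t_step <- t_step + 1
    }
  }
  assignment <- apply(x, 1, function(xi) {
    which.min(rowSums(sweep(W, 2, xi)^2))
  })
  names(assignment) <- rownames(x)
  structure(list(weights = W, grid = grid, assignment = assignment,
                 config = list(grid_rows = grid_rows, grid_cols = grid_cols,
                               learning_rate = learning_rate,
                               lr_constant = lr_constant, radius = radius,
                               epochs = epochs, seed = seed),
                 sample_ids = colnames(x)),
            class = "SOMModel")
}

# Linear initialization on the data manifold: the four profiles with extreme
# combined scores on the first two principal components anchor the grid
# corners and every unit is their bilinear blend. All prototypes are convex
# combinations of observed profiles, so no initial unit can exceed the data
# in any sample — off-manifold prototypes would be corrected only weakly by
# the fixed-radius neighborhood and would survive as spurious portrait
# extremes. Identical-profile inputs initialize every unit at that profile.
som_linear_init <- function(x, grid) {
  mu <- colMeans(x)
  sv <- svd(sweep(x, 2, mu), nu = 2, nv = 0)
  s1 <- sv$u[, 1] * sv$d[1]
  s2 <- if (length(sv$d) > 1) sv$u[, 2] * sv$d[2] else rep(0, nrow(x))
  corner <- function(a, b) x[which.max(a * s1 + b * s2), ]
  c00 <- corner(-1, -1); c01 <- corner(-1, 1)
  c10 <- corner(1, -1); c11 <- corner(1, 1)
  ax <- function(coord) {
    rng <- range(coord)
    if (diff(rng) == 0) rep(0.5, length(coord)) else
      (coord - rng[1]) / diff(rng)                  # [0, 1]
  }
  u <- ax(grid$row); v <- ax(grid$col)
  ((1 - u) * (1 - v)) %o% c00 + ((1 - u) * v) %o% c01 +
    (u * (1 - v)) %o% c10 + (u * v) %o% c11
}

#' @export
print.SOMModel <- function(x, ...) {
  cat(sprintf("SOMModel: %d x %d grid, %d profiles mapped, %d samples\n",
              x$config$grid_rows, x$config$grid_cols,
              length(x$assignment), ncol(x$weights)))
  invisible(x)
}

#' Portrait of one sample class
#'
#' The meta-PSF landscape of a class: for every grid unit, the mean of its
#' weight-vector entries over the class's samples, arranged on the grid.
#'
#' @param model A trained `SOMModel`.
#' @param sheet Sample sheet (see [read_sample_sheet()]); only samples that
#'   are columns of the training data are used.
#' @param class_label Class to portray.
#' @return Object of class `Portrait`: a `grid_rows x grid_cols` numeric
#'   matrix with attribute `class_label`.
#' @export
class_portrait <- function(model, sheet, class_label) {
  sheet <- read_sample_sheet(sheet)
  samples <- sheet$sample_id[sheet$class_label == class_label]
  samples <- intersect(samples, model$sample_ids)
  if (length(samples) == 0L) stop("unknown or empty class: ", class_label)
  cols <- match(samples, model$sample_ids)
  vals <- rowMeans(model$weights[, cols, drop = FALSE])
  p <- matrix(NA_real_, model$config$grid_rows, model$config$grid_cols)
  p[cbind(model$grid$row, model$grid$col)] <- vals
  structure(p, class_label = class_label, class = c("Portrait", "matrix", "array"))
}

#' Detect over- and under-expression spots on a portrait
#'
#' With the default threshold method, over-spots are the 4-connected
#' components of grid units whose value is at least
#' `threshold_fraction * max(portrait)` (only when the maximum is positive);
#' under-spots analogously use `threshold_fraction * min(portrait)` when the
#' minimum is negative. The default 0.90 reads the threshold as 90 percent of
#' the signed meta-PSF extreme. `method = "kmeans"` instead clusters the unit
#' values into three groups (seeded k-means) and takes the highest-center and
#' lowest-center groups as over-/under-units before the same connected-
#' component step.
#'
#' @param portrait A `Portrait`.
#' @param model Optional `SOMModel`; when given, each spot lists the sinks
#'   assigned to its units.
#' @param threshold_fraction Fraction of the extreme value (default 0.90).
#' @param method `"threshold"` (default) or `"kmeans"`.
#' @param seed Seed for the k-means variant.
#' @return Object of class `SpotSet`: list of spots, each with `polarity`
#'   (`"over"`/`"under"`), `units` (grid indices, row-major), `cells`
#'   (matrix of row/col coordinates), `peak` (extreme value in the spot) and
#'   `sinks` (character vector, possibly empty).
#' @export
detect_spots <- function(portrait, model = NULL, threshold_fraction = 0.90,
                         method = c("threshold", "kmeans"), seed = 1) {
  method <- match.arg(method)
  p <- unclass(portrait)
  if (max(p) - min(p) < .Machine$double.eps^0.5) {
    warning("constant portrait: no spots detectable")
    return(structure(list(), class = "SpotSet",
                     class_label = attr(portrait, "class_label")))
  }
  if (method == "threshold") {
    over_mask <- if (max(p) > 0) p >= threshold_fraction * max(p) else
      matrix(FALSE, nrow(p), ncol(p))
    under_mask <- if (min(p) < 0) p <= threshold_fraction * min(p) else
      matrix(FALSE, nrow(p), ncol(p))
  } else {
    km <- with_seed(seed, stats::kmeans(as.vector(p), centers = 3, nstart = 5))
    hi <- which.max(km$centers)
    lo <- which.min(km$centers)
    cl <- matrix(km$cluster, nrow(p), ncol(p))
    over_mask <- cl == hi & p > 0
    under_mask <- cl == lo & p < 0
  }
  spots <- c(mask_components(over_mask, p, "over"),
             mask_components(under_mask, p, "under"))
  if (!is.null(model)) {
    for (k in seq_along(spots)) {
      units <- spots[[k]]$units
      spots[[k]]$sinks <- names(model$assignment)[model$assignment %in% units]
    }
  }
  # order spots by descending absolute peak value for stable reporting
  if (length(spots)) {
    spots <- spots[order(-vapply(spots, function(s) abs(s$peak), 0))]
  }
  structure(spots, class = "SpotSet", class_label = attr(portrait, "class_label"))
}

# 4-connected components of a logical mask; returns a list of spot records
mask_components <- function(mask, p, polarity) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  spots <- list()
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    queue <- matrix(c(r0, c0), ncol = 2)
    seen[r0, c0] <- TRUE
    cells <- queue
    while (nrow(queue)) {
      cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r <- cur[1] + d[1]; c <- cur[2] + d[2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue <- rbind(queue, c(r, c))
          cells <- rbind(cells, c(r, c))
        }
      }
    }
    vals <- p[cells]
    spots[[length(spots) + 1L]] <- list(
      polarity = polarity,
      cells = unname(cells),
      units = as.integer((cells[, 1] - 1) * ncol(mask) + cells[, 2]),
      peak = if (polarity == "over") max(vals) else min(vals),
      sinks = character(0)
    )
  }
  spots
}

#' Summary spot map across classes
#'
#' Unions all over-expression spots of the per-class portraits on one grid;
#' overlapping class spots merge into lettered summary spots (A, B, ... by
#' descending peak value). Each summary spot reports its member units, the
#' sinks assigned to them, and the classes whose portraits activate it.
#'
#' @param spotsets Named list of `SpotSet` objects, one per class (names =
#'   class labels; unnamed lists fall back on the `class_label` attribute).
#' @param grid_rows,grid_cols Grid dimensions.
#' @return Object of class `SummarySpotMap`: list with `spots` (list of
#'   summary spots: `label`, `units`, `cells`, `peak`, `classes`, `sinks`)
#'   and `grid` (matrix of summary labels, `NA` off-spot).
#' @export
summary_spot_map <- function(spotsets, grid_rows, grid_cols) {
  labels <- names(spotsets)
  if (is.null(labels)) {
    labels <- vapply(spotsets, function(s) attr(s, "class_label") %||% NA_character_, "")
  }
  mask <- matrix(FALSE, grid_rows, grid_cols)
  peak <- matrix(-Inf, grid_rows, grid_cols)
  class_of_cell <- vector("list", grid_rows * grid_cols)
  sinks_of_cell <- vector("list", grid_rows * grid_cols)
  for (k in seq_along(spotsets)) {
    for (s in spotsets[[k]]) {
      if (s$polarity != "over") next
      for (j in seq_len(nrow(s$cells))) {
        r <- s$cells[j, 1]; c <- s$cells[j, 2]
        i <- (r - 1) * grid_cols + c
        mask[r, c] <- TRUE
        peak[r, c] <- max(peak[r, c], s$peak)
        class_of_cell[[i]] <- union(class_of_cell[[i]], labels[k])
        sinks_of_cell[[i]] <- union(sinks_of_cell[[i]], s$sinks)
      }
    }
  }
  comps <- mask_components(mask, peak, "over")
  if (length(comps)) {
    comps <- comps[order(-vapply(comps, `[[`, 0, "peak"))]
  }
  grid_lab <- matrix(NA_character_, grid_rows, grid_cols)
  spots <- list()
  for (k in seq_along(comps)) {
    lab <- make_spot_label(k)
    idx <- (comps[[k]]$cells[, 1] - 1) * grid_cols + comps[[k]]$cells[, 2]
    spots[[k]] <- list(
      label = lab,
      units = comps[[k]]$units,
      cells = comps[[k]]$cells,
      peak = comps[[k]]$peak,
      classes = sort(unique(unlist(class_of_cell[idx]))),
      sinks = sort(unique(unlist(sinks_of_cell[idx])))
    )
    grid_lab[comps[[k]]$cells] <- lab
  }
  structure(list(spots = spots, grid = grid_lab), class = "SummarySpotMap")
}

make_spot_label <- function(k) {
  if (k <= 26) LETTERS[k] else paste0(LETTERS[(k - 1) %/% 26], LETTERS[(k - 1) %% 26 + 1])
}

#' Render a portrait as an ASCII heatmap
#'
#' A quick terminal view of a portrait: values binned into a diverging
#' character ramp (`-` low, `.` mid, `+`/`#` high).
#'
#' @param portrait A `Portrait`.
#' @return Character vector of grid rows (also printed).
#' @export
portrait_ascii <- function(portrait) {
  p <- unclass(portrait)
  ramp <- c("-", ",", ".", " ", "'", "+", "#")
  ext <- max(abs(p), .Machine$double.eps)
  idx <- pmin(pmax(floor((p / ext + 1) / 2 * length(ramp)) + 1, 1), length(ramp))
  lines <- apply(matrix(ramp[idx], nrow(p), ncol(p)), 1, paste, collapse = "")
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Save / load a SOM model as portable text
#'
#' Writes the configuration and assignment as JSON plus the weight matrix as
#' TSV, so models survive without binary serialization.
#'
#' @param model A `SOMModel`.
#' @param dir Directory to write `som_model.json` and `som_weights.tsv` into.
#' @return `save_som_model`: the directory (invisibly). `load_som_model`: the
#'   restored `SOMModel`.
#' @export
save_som_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(config = model$config,
               assignment = as.list(model$assignment),
               sample_ids = model$sample_ids)
  jsonlite::write_json(meta, file.path(dir, "som_model.json"),
                       auto_unbox = TRUE, digits = NA)
  w <- model$weights
  rownames(w) <- paste0("unit", seq_len(nrow(w)))
  write_matrix_tsv(w, file.path(dir, "som_weights.tsv"), id_col = "unit")
  invisible(dir)
}

#' @rdname save_som_model
#' @export
load_som_model <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "som_model.json"),
                             simplifyVector = TRUE)
  w <- read_expression_tsv(file.path(dir, "som_weights.tsv"))
  rownames(w) <- NULL
  cfg <- meta$config
  grid <- data.frame(unit = seq_len(cfg$grid_rows * cfg$grid_cols),
                     row = rep(seq_len(cfg$grid_rows), each = cfg$grid_cols),
                     col = rep(seq_len(cfg$grid_cols), times = cfg$grid_rows))
  assignment <- unlist(meta$assignment)
  structure(list(weights = unname(w), grid = grid,
                 assignment = setNames(as.integer(assignment), names(assignment)),
                 config = cfg, sample_ids = meta$sample_ids),
            class = "SOMModel")
}
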