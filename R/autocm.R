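#' Auto-Contractive Map training configuration
#'
#' @param C Contraction constant, a positive real `>= 1` bounding every
#'   weight.  Default `NULL` means "number of input variables", which
#'   guarantees the contraction bound: the output-layer net input sums N
#'   terms each at most 1, so `Net/C <= 1`.
#' @param epsilon Initial value of every weight, `0 < epsilon < C`.  Zero
#'   is a fixed point of the learning rule, so a small strictly positive
#'   seed is required; a constant keeps training fully deterministic.
#' @param max_epochs Epoch cap.
#' @param tolerance Convergence threshold on the mean absolute weight
#'   change per epoch.
#' @param update_mode `"online"` applies deltas after every record;
#'   `"batch"` averages deltas over the epoch and applies them once
#'   (exactly record-order invariant).
#' @param record_order `"as-given"` or `"sorted-by-id"` (sorts records by
#'   row name before training).
#' @param symmetrization `"mean"` or `"max"`: how the asymmetric trained
#'   weight matrix is folded into a symmetric association matrix.
#' @param ls_normalization `"C"` divides symmetrized weights by `C`
#'   (absolute scale); `"max"` divides by the largest off-diagonal
#'   symmetrized weight (relative scale, strongest pair gets 1).
#' @return An `autocm_config` list.
#' @export
autocm_config <- function(C = NULL, epsilon = 0.01, max_epochs = 10000,
                          tolerance = 1e-6,
                          update_mode = c("online", "batch"),
                          record_order = c("as-given", "sorted-by-id"),
                          symmetrization = c("mean", "max"),
                          ls_normalization = c("C", "max")) {
  update_mode <- match.arg(update_mode)
  record_order <- match.arg(record_order)
  symmetrization <- match.arg(symmetrization)
  ls_normalization <- match.arg(ls_normalization)
  if (!is.null(C)) {
    if (!is.numeric(C) || length(C) != 1 || C < 1) {
      stop("C must be a single numeric >= 1 (or NULL for C = N)", call. = FALSE)
    }
    if (epsilon >= C) stop("epsilon must satisfy 0 < epsilon < C", call. = FALSE)
  }
  if (!is.numeric(epsilon) || epsilon <= 0) {
    stop("epsilon must satisfy 0 < epsilon < C", call. = FALSE)
  }
  if (max_epochs < 1) stop("max_epochs must be >= 1", call. = FALSE)
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  structure(list(C = C, epsilon = epsilon, max_epochs = max_epochs,
                 tolerance = tolerance, update_mode = update_mode,
                 record_order = record_order, symmetrization = symmetrization,
                 ls_normalization = ls_normalization),
            class = "autocm_config")
}

as_record_matrix <- function(dataset) {
  X <- if (inherits(dataset, "scaled_dataset")) dataset$records else as.matrix(dataset)
  if (!is.numeric(X)) stop("dataset must be numeric", call. = FALSE)
  if (anyNA(X)) stop("dataset contains missing values", call. = FALSE)
  if (any(X < 0) || any(X > 1)) {
    stop("AutoCM inputs must lie in [0, 1]; scale the data first", call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  X
}

#' Forward pass of an Auto-Contractive Map
#'
#' Propagates one record through the two contraction stages: the hidden
#' unit `m_h[i] = m_s[i] * (1 - v[i]/C)` contracts each input by its own
#' monodedicated weight, and the output unit
#' `m_t[i] = m_h[i] * (1 - Net[i]/C)` with
#' `Net[i] = sum_j w[i,j] * m_h[j] / C` contracts it again by the pooled
#' influence of all hidden units.
#'
#' @param model An `autocm` model (or any list with `v`, `w`, `C`).
#' @param record Numeric vector in `[0, 1]`, length equal to `length(v)`.
#' @return List with `hidden` and `output` vectors.
#' @export
autocm_forward <- function(model, record) {
  N <- length(model$v)
  if (length(record) != N) {
    stop("record length ", length(record), " does not match model size ", N,
         call. = FALSE)
  }
  mh <- record * (1 - model$v / model$C)
  net <- as.vector(model$w %*% mh) / model$C
  mt <- mh * (1 - net / model$C)
  list(hidden = mh, output = mt)
}

#' Learning deltas of an Auto-Contractive Map
#'
#' Computes (without applying) the weight updates for one record:
#' `dv[i] = (m_s[i] - m_h[i]) * (1 - v[i]/C)` and
#' `dw[i,j] = (m_h[i] - m_t[i]) * (1 - w[i,j]/C) * m_h[j]`.
#' On inputs in `[0, 1]` with weights in `[0, C)` every delta is
#' non-negative, so weights grow monotonically toward (and never beyond)
#' `C`; as `v` saturates the hidden signal vanishes and learning stops by
#' itself.
#'
#' @inheritParams autocm_forward
#' @return List with `dv` (vector) and `dw` (matrix).
#' @export
autocm_update <- function(model, record) {
  fp <- autocm_forward(model, record)
  dv <- (record - fp$hidden) * (1 - model$v / model$C)
  dw <- outer(fp$hidden - fp$output, fp$hidden) * (1 - model$w / model$C)
  list(dv = dv, dw = dw)
}

#' Train an Auto-Contractive Map
#'
#' Initializes every weight at `epsilon` and presents the records once per
#' epoch until the mean absolute weight change over an epoch falls below
#' `tolerance` (or `max_epochs` is reached, in which case a warning is
#' emitted and the model is returned with `converged = FALSE`).  Training
#' contains no randomness: identical data and configuration give
#' bit-identical models.
#'
#' The trained `w` matrix is read as a many-to-many association strength:
#' variable pairs that are repeatedly co-active accumulate larger mutual
#' weights during the saturation transient.  Use [autocm_distances()] and
#' [link_strengths()] to convert it.
#'
#' @param dataset A `scaled_dataset` from [assemble_dataset()], or a plain
#'   numeric matrix with entries in `[0, 1]` (rows = records).
#' @param config An [autocm_config()].
#' @return An `autocm` model: list with `v` (input-to-hidden weights), `w`
#'   (hidden-to-output weight matrix, row `i` = target unit), `C`,
#'   `epochs_run`, `converged`, `trace` (per-epoch mean `|dw|`),
#'   `variables`, and the `config` used.
#' @export
autocm_train <- function(dataset, config = autocm_config()) {
  stopifnot(inherits(config, "autocm_config"))
  X <- as_record_matrix(dataset)
  if (nrow(X) < 1) stop("dataset has no records", call. = FALSE)
  if (config$record_order == "sorted-by-id" && !is.null(rownames(X))) {
    X <- X[order(rownames(X)), , drop = FALSE]
  }
  N <- ncol(X)
  C <- if (is.null(config$C)) N else config$C
  if (config$epsilon >= C) {
    stop("epsilon (", config$epsilon, ") must be below C (", C, ")", call. = FALSE)
  }

  v <- rep(config$epsilon, N)
  w <- matrix(config$epsilon, N, N)
  trace <- numeric(0)
  converged <- FALSE
  epochs <- 0L

  for (ep in seq_len(config$max_epochs)) {
    w_before <- w
    if (config$update_mode == "online") {
      for (r in seq_len(nrow(X))) {
        ms <- X[r, ]
        mh <- ms * (1 - v / C)
        net <- as.vector(w %*% mh) / C
        mt <- mh * (1 - net / C)
        v <- v + (ms - mh) * (1 - v / C)
        w <- w + outer(mh - mt, mh) * (1 - w / C)
      }
    } else {
      dv <- numeric(N)
      dw <- matrix(0, N, N)
      for (r in seq_len(nrow(X))) {
        ms <- X[r, ]
        mh <- ms * (1 - v / C)
        net <- as.vector(w %*% mh) / C
        mt <- mh * (1 - net / C)
        dv <- dv + (ms - mh) * (1 - v / C)
        dw <- dw + outer(mh - mt, mh) * (1 - w / C)
      }
      v <- v + dv / nrow(X)
      w <- w + dw / nrow(X)
    }
    epochs <- ep
    trace[ep] <- mean(abs(w - w_before))
    if (trace[ep] < config$tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("AutoCM did not converge within ", config$max_epochs,
            " epochs (last mean |dw| = ", signif(trace[epochs], 3), ")",
            call. = FALSE)
  }
  dimnames(w) <- list(colnames(X), colnames(X))
  names(v) <- colnames(X)
  structure(list(v = v, w = w, C = C, epochs_run = epochs,
                 converged = converged, trace = trace,
                 variables = colnames(X), config = config),
            class = "autocm")
}

#' @export
print.autocm <- function(x, ...) {
  cat("Auto-Contractive Map:", length(x$v), "variables, C =", x$C, "\n")
  cat("  trained", x$epochs_run, "epochs,",
      if (x$converged) "converged" else "NOT converged",
      "(final mean |dw| =", signif(utils::tail(x$trace, 1), 3), ")\n")
  invisible(x)
}

#' Symmetrize a square matrix
#'
#' @param w Square numeric matrix.
#' @param method `"mean"` gives `(w + t(w)) / 2`; `"max"` the elementwise
#'   maximum of `w` and `t(w)`.
#' @return Symmetric matrix of the same dimension.
#' @export
symmetrize <- function(w, method = c("mean", "max")) {
  method <- match.arg(method)
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) stop("symmetrize() needs a square matrix", call. = FALSE)
  if (method == "mean") (w + t(w)) / 2 else pmax(w, t(w))
}

#' Convert trained AutoCM weights to distances
#'
#' Association weights become physical distances by `d = C - w_sym`
#' (diagonal forced to 0): pairs with stronger mutual weights lie strictly
#' nearer.  The result feeds the minimum-spanning-tree filter.
#'
#' @param model A trained `autocm` model.
#' @return Symmetric distance matrix with zero diagonal, entries in `[0, C]`.
#' @export
autocm_distances <- function(model) {
  stopifnot(inherits(model, "autocm"))
  if (any(model$w > model$C + 1e-12) || any(model$w < 0)) {
    stop("internal consistency error: trained weights outside [0, C]",
         call. = FALSE)
  }
  d <- model$C - symmetrize(model$w, model$config$symmetrization)
  diag(d) <- 0
  d
}

#' Link strengths of a trained AutoCM
#'
#' Normalizes the symmetrized weight matrix onto `[0, 1]`: 0 = no
#' association, 1 = maximal.  With the default `"C"` normalization
#' `ls = w_sym / C`, the algebraic complement of the distance
#' (`ls = 1 - d/C`); with `"max"` the strongest off-diagonal pair is
#' mapped to 1.
#'
#' @param model A trained `autocm` model.
#' @return Symmetric matrix in `[0, 1]` with unit diagonal.
#' @export
link_strengths <- function(model) {
  stopifnot(inherits(model, "autocm"))
  if (any(model$w > model$C + 1e-12) || any(model$w < 0)) {
    stop("internal consistency error: trained weights outside [0, C]",
         call. = FALSE)
  }
  ws <- symmetrize(model$w, model$config$symmetrization)
  ls <- if (model$config$ls_normalization == "C") {
    ws / model$C
  } else {
    off <- ws
    diag(off) <- NA
    mx <- max(off, na.rm = TRUE)
    if (mx <= 0) ws * 0 else pmin(ws / mx, 1)
  }
  diag(ls) <- 1
  ls
}

#' Serialize / load an AutoCM model as JSON
#'
#' Full-precision round trip: `read_autocm(write_autocm(m, f))` reproduces
#' the model exactly.
#'
#' @param model A trained `autocm` model.
#' @param path JSON file path.
#' @return `write_autocm()` the path invisibly; `read_autocm()` the model.
#' @export
write_autocm <- function(model, path) {
  stopifnot(inherits(model, "autocm"))
  payload <- list(
    variables = model$variables,
    C = model$C,
    v = unname(model$v),
    w = unname(model$w),   # serialized row-major below
    epochs_run = model$epochs_run,
    converged = model$converged,
    trace = model$trace,
    config = unclass(model$config)
  )
  payload$w <- as.vector(t(model$w))  # row-major
  # I(17) significant digits: enough for an exact double round trip
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_autocm
#' @export
read_autocm <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  N <- length(p$variables)
  w <- matrix(p$w, N, N, byrow = TRUE,
              dimnames = list(p$variables, p$variables))
  cfg <- p$config
  config <- autocm_config(C = cfg$C, epsilon = cfg$epsilon,
                          max_epochs = cfg$max_epochs,
                          tolerance = cfg$tolerance,
                          update_mode = cfg$update_mode,
                          record_order = cfg$record_order,
                          symmetrization = cfg$symmetrization,
                          ls_normalization = cfg$ls_normalization)
  structure(list(v = stats::setNames(p$v, p$variables), w = w, C = p$C,
                 epochs_run = p$epochs_run, converged = p$converged,
                 trace = p$trace, variables = p$variables, config = config),
            class = "autocm")
}
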