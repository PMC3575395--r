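#' Specify a synthetic cohort design
#'
#' A cohort design fixes everything [generate_cohort()] needs: per-group
#' subject counts, a per-(group, marker) mean table, shared latent factors
#' that induce within-group correlation blocks, independent Gaussian noise,
#' and clipping bounds.  Marker values are drawn as
#' `group mean + sum(loading * latent factor) + noise`, then clipped to
#' `[value_floor, value_cap]` - a truncated-Gaussian model of
#' flow-cytometry percentages with controllable correlations.
#'
#' @param group_sizes Named integer vector, subjects per phenotype group.
#' @param markers Character vector of marker names.
#' @param baseline_mean Named numeric vector (per marker), the group mean
#'   before any phenotype effect; units are percent of gated cells.
#' @param effects Numeric matrix (groups x markers) of additive mean
#'   shifts; zero means no phenotype effect on that marker.
#' @param correlation_blocks List of blocks, each a list with `markers`
#'   (character) and `loading` (scalar or one value per block marker, in
#'   `[-1, 1]`): one standard-normal-scaled latent factor of standard
#'   deviation `latent_sd` is drawn per subject per block and enters each
#'   block marker multiplied by its loading.
#' @param noise_sd Independent per-marker Gaussian noise standard
#'   deviation (scalar recycled, or named per marker), `> 0`.
#' @param latent_sd Standard deviation of every latent factor.
#' @param value_floor,value_cap Clipping bounds, `0 <= floor < cap`.
#' @return A validated `cohort_design`.
#' @export
cohort_design <- function(group_sizes, markers, baseline_mean, effects,
                          correlation_blocks = list(), noise_sd = 3,
                          latent_sd = 7.5, value_floor = 0.1, value_cap = 60) {
  groups <- names(group_sizes)
  if (is.null(groups) || any(groups == "")) {
    stop("group_sizes must be a named vector", call. = FALSE)
  }
  if (any(group_sizes <= 0) || any(group_sizes != round(group_sizes))) {
    stop("group sizes must be positive integers", call. = FALSE)
  }
  if (is.null(names(baseline_mean))) names(baseline_mean) <- markers
  if (!all(markers %in% names(baseline_mean))) {
    stop("baseline_mean must cover every marker", call. = FALSE)
  }
  baseline_mean <- baseline_mean[markers]
  effects <- as.matrix(effects)
  if (!all(rownames(effects) == groups) || !all(colnames(effects) == markers)) {
    stop("effects must be a groups x markers matrix with matching dimnames",
         call. = FALSE)
  }
  if (length(noise_sd) == 1) noise_sd <- stats::setNames(rep(noise_sd, length(markers)), markers)
  noise_sd <- noise_sd[markers]
  if (any(is.na(noise_sd)) || any(noise_sd <= 0)) {
    stop("noise_sd must be > 0 for every marker", call. = FALSE)
  }
  if (value_floor < 0 || value_cap <= value_floor) {
    stop("need 0 <= value_floor < value_cap", call. = FALSE)
  }
  for (b in correlation_blocks) {
    if (!all(b$markers %in% markers)) {
      stop("correlation block names unknown marker(s): ",
           paste(setdiff(b$markers, markers), collapse = ", "), call. = FALSE)
    }
    if (any(abs(b$loading) > 1)) {
      stop("latent-factor loadings must lie in [-1, 1]", call. = FALSE)
    }
    if (!length(b$loading) %in% c(1L, length(b$markers))) {
      stop("block loading must be scalar or one value per block marker",
           call. = FALSE)
    }
  }
  mean_table <- sweep(effects, 2, baseline_mean, "+")
  if (any(mean_table < value_floor) || any(mean_table > value_cap)) {
    stop("some group means fall outside [value_floor, value_cap]",
         call. = FALSE)
  }
  structure(list(group_sizes = group_sizes, markers = markers,
                 baseline_mean = baseline_mean, effects = effects,
                 correlation_blocks = correlation_blocks,
                 noise_sd = noise_sd, latent_sd = latent_sd,
                 value_floor = value_floor, value_cap = value_cap),
            class = "cohort_design")
}

#' Marginal within-group standard deviation implied by a design
#'
#' Per marker: `sqrt(sum((loading * latent_sd)^2) + noise_sd^2)` over the
#' blocks the marker belongs to (before clipping).
#'
#' @param design A `cohort_design`, or the pieces thereof.
#' @return Named numeric vector per marker.
#' @export
design_within_sd <- function(design) {
  var_total <- design$noise_sd^2
  for (b in design$correlation_blocks) {
    loading <- rep(b$loading, length.out = length(b$markers))
    var_total[b$markers] <- var_total[b$markers] +
      (loading * design$latent_sd)^2
  }
  sqrt(var_total)
}

#' Default synthetic MS cohort design
#'
#' Emulates the reference study's cohort: 30 RR, 26 BB, 33 SP, 14 PP and
#' 42 HC subjects over the 11-marker panel, with the planted
#' phenotype-marker structure reported for the real cohort:
#' \itemize{
#'   \item CD4+IL25+ lowered in SP, PP and HC, raised in RR;
#'   \item CD4+RORC+ raised in SP only (the healthy controls share the low
#'     IL-25 signature but not the inflammatory one);
#'   \item CD4+IL13+ and CD14+IL6+ raised in BB;
#'   \item a latent factor coupling CD4+IL25+ and CD4+IL13+ (the IL-25 to
#'     IL-13 induction axis) at loading 0.8;
#'   \item a latent factor coupling CD4+IL13+ and CD14+IL6+ (the
#'     anti-/pro-inflammatory pairing that characterizes the benign arm);
#'   \item a phenotype-free latent factor coupling CD4+IL9+ with
#'     CD4+GATA+, CD4+TBET+ and CD4+IL22+ - the Th9 cluster that sits
#'     apart from the disease-related part of the network.
#' }
#' Every phenotype effect is 1.5 within-group standard deviations of the
#' affected marker.  Baselines sit mid-scale (15%, IL-25 at 20%) with
#' clipping to `[0.1, 60]`, the percent range quoted for the real panel.
#'
#' @return A `cohort_design`.
#' @export
default_ms_design <- function() {
  markers <- ms_markers()
  groups <- ms_phenotypes()
  sizes <- c(RR = 30L, BB = 26L, SP = 33L, PP = 14L, HC = 42L)
  baseline <- stats::setNames(rep(15, length(markers)), markers)
  baseline["CD4+IL25+"] <- 20

  blocks <- list(
    list(markers = c("CD4+IL25+", "CD4+IL13+"), loading = 0.8),
    list(markers = c("CD4+IL9+", "CD4+GATA+", "CD4+TBET+", "CD4+IL22+"),
         loading = 0.8),
    list(markers = c("CD4+IL13+", "CD14+IL6+"), loading = c(0.55, 0.8)))

  noise_sd <- 3
  latent_sd <- 7.5
  tmp <- list(markers = markers,
              noise_sd = stats::setNames(rep(noise_sd, length(markers)), markers),
              latent_sd = latent_sd, correlation_blocks = blocks)
  sd_within <- design_within_sd(tmp)
  shift <- 1.5 * sd_within

  effects <- matrix(0, length(groups), length(markers),
                    dimnames = list(groups, markers))
  effects["RR", "CD4+IL25+"] <- shift[["CD4+IL25+"]]
  effects[c("SP", "PP", "HC"), "CD4+IL25+"] <- -shift[["CD4+IL25+"]]
  effects["SP", "CD4+RORC+"] <- shift[["CD4+RORC+"]]
  effects["BB", "CD4+IL13+"] <- shift[["CD4+IL13+"]]
  effects["BB", "CD14+IL6+"] <- shift[["CD14+IL6+"]]

  cohort_design(group_sizes = sizes, markers = markers,
                baseline_mean = baseline, effects = effects,
                correlation_blocks = blocks, noise_sd = noise_sd,
                latent_sd = latent_sd, value_floor = 0.1, value_cap = 60)
}

#' Generate a synthetic cohort
#'
#' Draws a subject x marker table from a [cohort_design()].  Per subject,
#' one latent factor per correlation block is drawn, then each marker
#' value is `group mean + sum(loading * factor) + Gaussian noise`, clipped
#' to the design bounds.  The table is fully determined by the seed; the
#' caller's RNG state is left untouched.
#'
#' @param design A `cohort_design`.
#' @param seed Integer seed.
#' @param size_multiplier Scales every group count (used by convergence
#'   checks at inflated sample sizes).
#' @return `data.frame` with `subject_id`, `phenotype` and one column per
#'   marker, in the same CSV dialect [read_marker_table()] expects.
#' @export
generate_cohort <- function(design, seed, size_multiplier = 1) {
  stopifnot(inherits(design, "cohort_design"))
  if (length(seed) != 1 || is.na(seed)) stop("seed must be a single integer",
                                             call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  groups <- names(design$group_sizes)
  markers <- design$markers
  nb <- length(design$correlation_blocks)
  rows <- list()
  for (g in groups) {
    n_g <- design$group_sizes[[g]] * size_multiplier
    mu <- design$baseline_mean + design$effects[g, ]
    for (i in seq_len(n_g)) {
      val <- mu + stats::rnorm(length(markers), 0, design$noise_sd)
      if (nb > 0) {
        f <- stats::rnorm(nb, 0, design$latent_sd)
        for (b in seq_len(nb)) {
          blk <- design$correlation_blocks[[b]]
          loading <- rep(blk$loading, length.out = length(blk$markers))
          val[blk$markers] <- val[blk$markers] + loading * f[b]
        }
      }
      val <- pmin(pmax(val, design$value_floor), design$value_cap)
      rows[[length(rows) + 1L]] <-
        c(list(subject_id = sprintf("%s_%03d", g, i), phenotype = g),
          as.list(val))
    }
  }
  ids <- vapply(rows, `[[`, "", "subject_id")
  phen <- vapply(rows, `[[`, "", "phenotype")
  vals <- t(vapply(rows, function(r) unlist(r[markers]), numeric(length(markers))))
  colnames(vals) <- markers
  out <- data.frame(subject_id = ids, phenotype = phen,
                    stringsAsFactors = FALSE, check.names = FALSE)
  cbind(out, as.data.frame(vals, check.names = FALSE))
}

#' Write / read a cohort design as YAML
#'
#' @param design A `cohort_design`.
#' @param path YAML file path.
#' @return `write_design()` the path invisibly; `read_design()` the
#'   validated `cohort_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "cohort_design"))
  payload <- list(
    group_sizes = as.list(design$group_sizes),
    markers = design$markers,
    baseline_mean = as.list(design$baseline_mean),
    effects = lapply(rownames(design$effects), function(g) {
      as.list(design$effects[g, ])
    }),
    correlation_blocks = lapply(design$correlation_blocks, function(b) {
      list(markers = b$markers, loading = b$loading)
    }),
    noise_sd = as.list(design$noise_sd),
    latent_sd = design$latent_sd,
    value_floor = design$value_floor,
    value_cap = design$value_cap)
  names(payload$effects) <- rownames(design$effects)
  yaml::write_yaml(payload, path, precision = 17)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  p <- yaml::read_yaml(path)
  groups <- names(p$group_sizes)
  markers <- unlist(p$markers)
  effects <- do.call(rbind, lapply(p$effects, function(e) unlist(e)[markers]))
  rownames(effects) <- names(p$effects)
  colnames(effects) <- markers
  cohort_design(
    group_sizes = unlist(p$group_sizes),
    markers = markers,
    baseline_mean = unlist(p$baseline_mean),
    effects = effects[groups, , drop = FALSE],
    correlation_blocks = lapply(p$correlation_blocks, function(b) {
      list(markers = unlist(b$markers), loading = unlist(b$loading))
    }),
    noise_sd = unlist(p$noise_sd),
    latent_sd = p$latent_sd,
    value_floor = p$value_floor,
    value_cap = p$value_cap)
}
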