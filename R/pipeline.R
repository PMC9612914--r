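#' Convert a property-pair dataset into a size-referenced dataset
#'
#' Maps the regressor column of a normalized `{A; B}` global dataset
#' through an inverse size law `S = f(B)`, yielding an intermediary
#' `{A; S_MN}` dataset. The response values are untouched and per-point
#' provenance is kept. With `renormalize = TRUE` (default) the mapped size
#' column of each contributing study is then re-expressed as percent of its
#' own maximum, the same convention under which directly measured size
#' columns enter the pipeline; this keeps every intermediary dataset in one
#' common normalized space (it is the identity on noiseless data) and
#' prevents spurious offsets between transformed and directly measured
#' clouds when they are merged.
#'
#' @param gds Normalized `global_dataset` for pair `{A; B}`.
#' @param inv A `power_law` mapping `B` to size (`prop_y` is the size
#'   property, `prop_x = B`). Ignored if `gds` is already size-referenced.
#' @param size_prop Name of the size property, default `"S_MN"`.
#' @param renormalize Re-express transformed sizes as percent of the
#'   per-study maximum.
#' @return A `global_dataset` for `{A; size_prop}` with the same number of
#'   points.
#' @export
transform_to_size <- function(gds, inv = NULL, size_prop = "S_MN",
                              renormalize = TRUE) {
  stopifnot(inherits(gds, "global_dataset"))
  if (identical(gds$prop_x, size_prop)) return(gds)
  if (is.null(inv)) {
    stop("no inverse size law supplied for regressor '", gds$prop_x, "'",
         call. = FALSE)
  }
  stopifnot(inherits(inv, "power_law"))
  if (!identical(inv$prop_x, gds$prop_x) ||
      !identical(inv$prop_y, size_prop)) {
    stop("inverse law maps ", inv$prop_x, " to ", inv$prop_y,
         " but dataset needs ", gds$prop_x, " to ", size_prop,
         call. = FALSE)
  }
  s <- predict(inv, gds$x)
  if (renormalize) {
    for (st in unique(gds$study)) {
      i <- gds$study == st
      s[i] <- 100 * s[i] / max(s[i])
    }
  }
  out <- gds
  out$x <- s
  out$prop_x <- size_prop
  out
}

#' Derive the size-referenced relationship framework
#'
#' Implements the step-by-step derivation of normalized size-dependent
#' power laws. Properties are processed in a fixed order (default ACV, AHP,
#' R, I_th, C, tau). For each property A, every available `{A; B}` global
#' dataset is converted to an `{A; S_MN}` dataset: directly if `B` is size,
#' otherwise through the inverse size law of an already processed `B`. The
#' converted datasets are concatenated into the final `{A; S_MN}` dataset,
#' to which a power law `A = k_c S^c` is fitted. If the fit passes the
#' admission gate (`r2 > 0.3`, i.e. |r| > 0.55, and `p < 0.01`) an inverse
#' law `S = f(A)` is derived for use with the next properties; by default
#' the inverse is the analytic inversion of the final fit, with an
#' axis-swapped OLS refit available via `inverse_method = "refit"`.
#' Afterwards, every ordered pair of processed properties receives a
#' derived law by composing the size laws, so the pairwise laws are exactly
#' consistent with the size laws by construction.
#'
#' @param globals List of normalized `global_dataset`s.
#' @param order Processing order of properties; the first must have a
#'   directly size-referenced dataset.
#' @param size_prop Size property name in `globals` (default `"S_MN"`).
#' @param gate_r2,gate_p Admission gate on the final fit for deriving the
#'   inverse law.
#' @param inverse_method `"analytic"` or `"refit"` (see [invert_power()]).
#' @param renormalize Passed to [transform_to_size()].
#' @return A `relationship_set`: size laws, admitted inverse laws, derived
#'   pairwise laws, final datasets, and the gate decision table.
#' @export
derive_relationships <- function(globals,
                                 order = c("ACV", "AHP", "R", "I_th",
                                           "C", "tau"),
                                 size_prop = "S_MN",
                                 gate_r2 = 0.3, gate_p = 0.01,
                                 inverse_method = c("analytic", "refit"),
                                 renormalize = TRUE) {
  inverse_method <- match.arg(inverse_method)
  stopifnot(all(vapply(globals, inherits, TRUE, "global_dataset")))
  if (!all(vapply(globals, `[[`, TRUE, "normalized"))) {
    stop("all global datasets must be normalized", call. = FALSE)
  }
  props_y <- vapply(globals, `[[`, "", "prop_y")
  order <- intersect(order, unique(props_y))
  if (length(order) == 0) stop("no processable properties", call. = FALSE)

  size_laws <- list()
  inverse_laws <- list()
  final_datasets <- list()
  gates <- data.frame()

  for (A in order) {
    sources <- globals[props_y == A]
    usable <- vapply(sources, function(g) {
      identical(g$prop_x, size_prop) || g$prop_x %in% names(inverse_laws)
    }, TRUE)
    dropped <- vapply(sources[!usable], `[[`, "", "prop_x")
    if (length(dropped)) {
      stop("property '", A, "' references '",
           paste(dropped, collapse = "', '"),
           "' for which no admitted inverse size law exists; ",
           "check the processing order and gate decisions", call. = FALSE)
    }
    if (!length(sources)) {
      stop("property '", A, "' has no source dataset", call. = FALSE)
    }
    converted <- lapply(sources, function(g) {
      transform_to_size(g, inverse_laws[[g$prop_x]], size_prop,
                        renormalize = renormalize)
    })
    fin <- list(
      prop_x = size_prop, prop_y = A,
      x = unlist(lapply(converted, `[[`, "x"), use.names = FALSE),
      y = unlist(lapply(converted, `[[`, "y"), use.names = FALSE),
      study = unlist(lapply(converted, `[[`, "study"), use.names = FALSE),
      source_pair = unlist(lapply(seq_along(converted), function(i)
        rep(sources[[i]]$prop_x, length(converted[[i]]$x))),
        use.names = FALSE),
      species = sources[[1]]$species,
      normalized = TRUE
    )
    class(fin) <- "global_dataset"
    law <- fit_power(fin$x, fin$y, prop_x = size_prop, prop_y = A,
                     space = "normalized")
    admitted <- is.finite(law$r2) && law$r2 > gate_r2 && law$p < gate_p
    gates <- rbind(gates, data.frame(
      property = A, n = law$n, r2 = law$r2, p = law$p,
      inverse_admitted = admitted
    ))
    size_laws[[A]] <- law
    final_datasets[[A]] <- fin
    if (admitted) {
      inverse_laws[[A]] <- if (inverse_method == "refit") {
        invert_power(law, method = "refit", x = fin$x, y = fin$y)
      } else {
        invert_power(law)
      }
    }
  }

  pairwise <- list()
  for (A in names(size_laws)) {
    for (B in names(size_laws)) {
      if (A == B) next
      pairwise[[paste(A, B, sep = "~")]] <-
        compose_power(size_laws[[A]], invert_power(size_laws[[B]]))
    }
  }

  structure(list(
    size_prop = size_prop,
    space = "normalized",
    order = names(size_laws),
    size_laws = size_laws,
    inverse_laws = inverse_laws,
    pairwise = pairwise,
    final_datasets = final_datasets,
    gates = gates
  ), class = "relationship_set")
}

#' Look up a relationship in a relationship set
#'
#' Returns the law `prop_y = f(prop_x)`. Size laws and their inverses are
#' served directly; other pairs come from the precomputed composed laws or,
#' in a bundled absolute framework, by composing through the size property.
#'
#' @param rs A `relationship_set`.
#' @param prop_y,prop_x Property names.
#' @return A `power_law`.
#' @export
relationship <- function(rs, prop_y, prop_x) {
  stopifnot(inherits(rs, "relationship_set"))
  if (identical(prop_y, prop_x)) {
    return(power_law(1, 1, prop_y, prop_x, space = rs$space,
                     provenance = "identity"))
  }
  if (identical(prop_x, rs$size_prop) && prop_y %in% names(rs$size_laws)) {
    return(rs$size_laws[[prop_y]])
  }
  if (identical(prop_y, rs$size_prop) && prop_x %in% names(rs$size_laws)) {
    return(invert_power(rs$size_laws[[prop_x]]))
  }
  key <- paste(prop_y, prop_x, sep = "~")
  if (key %in% names(rs$pairwise)) return(rs$pairwise[[key]])
  if (prop_y %in% names(rs$size_laws) && prop_x %in% names(rs$size_laws)) {
    return(compose_power(rs$size_laws[[prop_y]],
                         invert_power(rs$size_laws[[prop_x]])))
  }
  stop("no relationship between '", prop_y, "' and '", prop_x,
       "' in this set", call. = FALSE)
}

#' @export
print.relationship_set <- function(x, ...) {
  cat(sprintf("relationship_set (%s space, size property %s)\n",
              x$space, x$size_prop))
  for (A in names(x$size_laws)) print(x$size_laws[[A]])
  invisible(x)
}

#' Prediction-accuracy metrics
#'
#' Scores predictions of positive values with the three validation
#' metrics: normalized maximum error `nME` (largest per-point relative
#' error, percent -- values above 100% are possible), normalized root mean
#' squared error `nRMSE` (RMSE over the mean of the observed values,
#' percent), and a prediction r-squared. Config switches select the
#' range-normalized alternatives: `nme = "range"` and `nrmse = "range"`
#' divide by the observed range instead; `r2 = "ss"` uses
#' `1 - SS_res/SS_tot` instead of the squared Pearson correlation.
#'
#' @param observed,predicted Positive paired vectors.
#' @param nme,nrmse `"relative"`/`"mean"` (defaults) or `"range"`.
#' @param r2 `"cor"` (default) or `"ss"`.
#' @return List with `nME`, `nRMSE`, `r2` (percent, percent, unitless).
#' @export
prediction_metrics <- function(observed, predicted,
                               nme = c("relative", "range"),
                               nrmse = c("mean", "range"),
                               r2 = c("cor", "ss")) {
  nme <- match.arg(nme); nrmse <- match.arg(nrmse); r2 <- match.arg(r2)
  stopifnot(length(observed) == length(predicted))
  err <- predicted - observed
  nME <- if (nme == "relative") {
    100 * max(abs(err) / observed)
  } else {
    100 * max(abs(err)) / (max(observed) - min(observed))
  }
  rmse <- sqrt(mean(err^2))
  nRMSE <- if (nrmse == "mean") {
    100 * rmse / mean(observed)
  } else {
    100 * rmse / (max(observed) - min(observed))
  }
  r2v <- if (r2 == "cor") {
    if (stats::var(predicted) == 0 || stats::var(observed) == 0) {
      if (all(err == 0)) 1 else 0
    } else {
      stats::cor(observed, predicted)^2
    }
  } else {
    1 - sum(err^2) / sum((observed - mean(observed))^2)
  }
  list(nME = nME, nRMSE = nRMSE, r2 = r2v)
}

#' Fivefold cross-validation of a fitted relationship
#'
#' Shuffles the points of a normalized global dataset (seeded), splits them
#' into `folds` non-overlapping partitions, and for each permutation fits
#' the power law on the training 80% and scores the held-out 20% with
#' [prediction_metrics()]. Metrics are averaged over the permutations;
#' `r2exp` is the r-squared of the fit to the complete dataset, against
#' which the averaged prediction r-squared is compared. Reruns with the
#' same seed are bit-identical.
#'
#' @param gds A `global_dataset` with at least 10 points.
#' @param folds Number of folds (default 5).
#' @param seed Shuffling seed (default 0).
#' @param ... Metric-definition switches passed to [prediction_metrics()].
#' @return A `cv_report`: per-permutation metric table, averaged `nME`,
#'   `nRMSE`, `r2pred`, the full-fit `r2exp`, fold assignments and seed.
#' @export
crossvalidate <- function(gds, folds = 5, seed = 0, ...) {
  stopifnot(inherits(gds, "global_dataset"))
  n <- length(gds$x)
  if (n < 10) stop("need at least 10 points for cross-validation",
                   call. = FALSE)
  if (floor(n / folds) < 2) stop("fewer than 2 points per fold",
                                 call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  fold_of <- integer(n)
  fold_of[perm] <- rep_len(seq_len(folds), n)
  rows <- lapply(seq_len(folds), function(f) {
    test <- fold_of == f
    fit <- fit_power(gds$x[!test], gds$y[!test],
                     prop_x = gds$prop_x, prop_y = gds$prop_y,
                     space = "normalized")
    m <- prediction_metrics(gds$y[test], predict(fit, gds$x[test]), ...)
    data.frame(permutation = f, n_test = sum(test),
               nME = m$nME, nRMSE = m$nRMSE, r2pred = m$r2)
  })
  tab <- do.call(rbind, rows)
  full <- fit_power(gds$x, gds$y, prop_x = gds$prop_x, prop_y = gds$prop_y,
                    space = "normalized")
  structure(list(
    pair = c(gds$prop_y, gds$prop_x),
    folds = folds, seed = seed,
    permutations = tab,
    nME = mean(tab$nME), nRMSE = mean(tab$nRMSE),
    r2pred = mean(tab$r2pred), r2exp = full$r2,
    fold_assignment = fold_of
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "fivefold CV {%s; %s}: nME %.1f%%, nRMSE %.1f%%, r2pred %.3f (r2exp %.3f)\n",
    x$pair[1], x$pair[2], x$nME, x$nRMSE, x$r2pred, x$r2exp))
  invisible(x)
}
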