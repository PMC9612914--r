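#' Per-study paired dataset of two motoneuron properties
#'
#' A `study_dataset` holds the cloud of concurrently measured values of one
#' property pair `{A; B}` reported by a single study: `y` is property A
#' (`prop_y`), `x` is property B (`prop_x`). Values are strictly positive;
#' a normalized dataset has each column expressed as percent of its own
#' within-study maximum, so both columns peak at 100.
#'
#' @param study_id Study identifier.
#' @param species One of `"cat"`, `"rat"`, `"mouse"`.
#' @param prop_x,prop_y Property names (see [mn_properties()]).
#' @param x,y Paired strictly positive values (SI unless normalized).
#' @param normalized Logical; whether columns are percent-of-maximum.
#' @return A `study_dataset`.
#' @export
study_dataset <- function(study_id, species, prop_x, prop_y, x, y,
                          normalized = FALSE) {
  species <- match.arg(species, c("cat", "rat", "mouse"))
  if (!is_known_property(prop_x)) stop("unknown property '", prop_x, "'",
                                       call. = FALSE)
  if (!is_known_property(prop_y)) stop("unknown property '", prop_y, "'",
                                       call. = FALSE)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) == 0) stop("empty dataset", call. = FALSE)
  stopifnot_positive(x, "x"); stopifnot_positive(y, "y")
  if (normalized) {
    if (abs(max(x) - 100) > 1e-8 || abs(max(y) - 100) > 1e-8) {
      stop("normalized dataset must have column maxima equal to 100",
           call. = FALSE)
    }
  }
  structure(list(
    study_id = as.character(study_id), species = species,
    prop_x = prop_x, prop_y = prop_y,
    x = as.numeric(x), y = as.numeric(y),
    normalized = isTRUE(normalized)
  ), class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("study_dataset %s (%s): {%s; %s}, n = %d, %s\n",
              x$study_id, x$species, x$prop_y, x$prop_x, length(x$x),
              if (x$normalized) "normalized (% max)" else "absolute units"))
  invisible(x)
}

#' Read study datasets from a tabular file
#'
#' The documented CSV schema (version 1) has the header
#' `study_id, species, prop_x, prop_y, x, y, unit_x, unit_y`, UTF-8,
#' decimal point. Values are converted to SI on load; rows with missing or
#' non-positive entries are dropped (not clamped) with a warning counting
#' them, since the downstream log transform cannot accept them.
#'
#' `load_corpus` returns one `study_dataset` per `(study_id, prop_y,
#' prop_x)` block in the file; `load_study_data` expects exactly one block.
#'
#' @param path Path to a CSV file following the schema.
#' @return A list of `study_dataset`s (`load_corpus`) or a single
#'   `study_dataset` (`load_study_data`).
#' @export
load_corpus <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "species", "prop_x", "prop_y", "x", "y",
            "unit_x", "unit_y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_prop <- setdiff(unique(c(df$prop_x, df$prop_y)),
                      mn_properties()$property)
  if (length(bad_prop)) {
    stop("schema error: unknown properties ",
         paste(bad_prop, collapse = ", "), call. = FALSE)
  }
  df$x <- suppressWarnings(as.numeric(df$x))
  df$y <- suppressWarnings(as.numeric(df$y))
  usable <- is.finite(df$x) & is.finite(df$y) & df$x > 0 & df$y > 0
  if (any(!usable)) {
    warning(sum(!usable), " row(s) with missing or non-positive values ",
            "dropped from ", basename(path), call. = FALSE)
    df <- df[usable, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no usable rows in ", path, call. = FALSE)
  key <- paste(df$study_id, df$prop_y, df$prop_x, sep = "\r")
  blocks <- split(df, factor(key, levels = unique(key)))
  out <- lapply(blocks, function(b) {
    study_dataset(
      study_id = b$study_id[1], species = b$species[1],
      prop_x = b$prop_x[1], prop_y = b$prop_y[1],
      x = to_si(b$x, b$unit_x[1]), y = to_si(b$y, b$unit_y[1])
    )
  })
  names(out) <- vapply(out, function(d)
    paste(d$study_id, d$prop_y, d$prop_x, sep = "."), "")
  out
}

#' @rdname load_corpus
#' @export
load_study_data <- function(path) {
  out <- load_corpus(path)
  if (length(out) != 1) {
    stop("expected a single (study, pair) block, found ", length(out),
         "; use load_corpus()", call. = FALSE)
  }
  out[[1]]
}

#' Normalize a study dataset to percent of its own maxima
#'
#' Each column is independently rescaled so its within-study maximum maps
#' to 100. This absorbs the multiplicative scale offsets between studies
#' (electrode, protocol, cohort differences) under the assumption that
#' studies sampled comparable portions of the motoneuron pool. The
#' operation is scale-invariant (`normalize(c * X)` equals `normalize(X)`
#' for any `c > 0`) and may only be applied once.
#'
#' @param ds An unnormalized `study_dataset`.
#' @return The normalized `study_dataset`.
#' @export
normalize_study <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  if (ds$normalized) {
    stop("dataset ", ds$study_id, " is already normalized", call. = FALSE)
  }
  ds$x <- 100 * ds$x / max(ds$x)
  ds$y <- 100 * ds$y / max(ds$y)
  ds$normalized <- TRUE
  ds
}

#' Merge normalized study datasets into a global dataset
#'
#' Concatenates the normalized point clouds of several studies reporting
#' the same property pair, keeping per-point study provenance and
#' within-study point order. No reweighting is applied: every point counts
#' once, so large studies dominate in proportion to their size.
#'
#' @param members List of normalized `study_dataset`s sharing one pair.
#' @return A `global_dataset` with fields `prop_x`, `prop_y`, `x`, `y`,
#'   `study` (per-point provenance), `species`, `normalized`.
#' @export
merge_global <- function(members) {
  if (inherits(members, "study_dataset")) members <- list(members)
  if (length(members) < 1) stop("no member datasets", call. = FALSE)
  ok <- vapply(members, inherits, TRUE, "study_dataset")
  if (!all(ok)) stop("members must be study_datasets", call. = FALSE)
  px <- unique(vapply(members, `[[`, "", "prop_x"))
  py <- unique(vapply(members, `[[`, "", "prop_y"))
  if (length(px) != 1 || length(py) != 1) {
    stop("pair mismatch: members report different property pairs",
         call. = FALSE)
  }
  if (!all(vapply(members, `[[`, TRUE, "normalized"))) {
    stop("all members must be normalized before merging", call. = FALSE)
  }
  sp <- unique(vapply(members, `[[`, "", "species"))
  if (length(sp) != 1) {
    stop("species mixing within a global dataset is not supported",
         call. = FALSE)
  }
  structure(list(
    prop_x = px, prop_y = py,
    x = unlist(lapply(members, `[[`, "x"), use.names = FALSE),
    y = unlist(lapply(members, `[[`, "y"), use.names = FALSE),
    study = unlist(lapply(members, function(d)
      rep(d$study_id, length(d$x))), use.names = FALSE),
    species = sp,
    normalized = TRUE
  ), class = "global_dataset")
}

#' Construct a global dataset directly from vectors
#'
#' Used for absolute-SI datasets (e.g. external-species scoring) where the
#' per-study normalization machinery is not involved.
#'
#' @param prop_x,prop_y Property names.
#' @param x,y Paired positive values.
#' @param study Per-point provenance labels.
#' @param species Species label.
#' @param normalized Whether values are percent-of-maximum.
#' @return A `global_dataset`.
#' @export
global_dataset <- function(prop_x, prop_y, x, y,
                           study = "pooled", species = "cat",
                           normalized = FALSE) {
  stopifnot_positive(x, "x"); stopifnot_positive(y, "y")
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  structure(list(
    prop_x = prop_x, prop_y = prop_y,
    x = as.numeric(x), y = as.numeric(y),
    study = rep_len(as.character(study), length(x)),
    species = species, normalized = isTRUE(normalized)
  ), class = "global_dataset")
}

#' @export
print.global_dataset <- function(x, ...) {
  cat(sprintf("global_dataset {%s; %s}: %d points from %d study(ies), %s\n",
              x$prop_y, x$prop_x, length(x$x), length(unique(x$study)),
              if (x$normalized) "normalized" else "absolute"))
  invisible(x)
}

#' Distribution variability metrics
#'
#' The four descriptors used to compare property distributions across
#' studies: the range (max - min, data units), the mean, the coefficient of
#' variation (sample sd / mean, dimensionless) and the median-to-mean ratio
#' (skewness indicator; 1 for a symmetric sample). The median uses the
#' midpoint convention for even counts; the sd is the sample (n-1)
#' estimator.
#'
#' @param values At least two positive values.
#' @return List with `range`, `mean`, `cov`, `me_md`.
#' @examples
#' distribution_metrics(c(1, 2, 3))  # range 2, mean 2, cov 0.5, me_md 1
#' @export
distribution_metrics <- function(values) {
  if (length(values) < 2) {
    stop("need at least 2 values for distribution metrics", call. = FALSE)
  }
  stopifnot_positive(values, "values")
  m <- mean(values)
  list(
    range = max(values) - min(values),
    mean = m,
    cov = stats::sd(values) / m,
    me_md = stats::median(values) / m
  )
}

#' Inter-study (or inter-global-dataset) homogeneity check
#'
#' Computes, for each of the four distribution metrics, the mean and sample
#' sd across the supplied per-study metric sets, and flags a metric as
#' homogeneous when `sd_g < 10` (percent units, so metrics must come from
#' normalized distributions) and `sd_g / mean_g < 0.15`. The same routine
#' serves the inter-global-dataset variant (`sd_G`, `mean_G`): supply one
#' metric set per global dataset. With a single study the sd is undefined
#' and every flag is `NA` (not assessable).
#'
#' @param metric_sets List of [distribution_metrics()] results computed on
#'   normalized (percent) distributions.
#' @return Data.frame with one row per metric: `mean_g`, `sd_g`, `ratio`,
#'   `homogeneous`.
#' @export
homogeneity_check <- function(metric_sets) {
  if (length(metric_sets) < 1) stop("no metric sets", call. = FALSE)
  metrics <- c("range", "mean", "cov", "me_md")
  rows <- lapply(metrics, function(mname) {
    v <- vapply(metric_sets, function(s) s[[mname]], 0)
    if (length(v) < 2) {
      data.frame(metric = mname, mean_g = mean(v), sd_g = NA_real_,
                 ratio = NA_real_, homogeneous = NA)
    } else {
      sd_g <- stats::sd(v)
      data.frame(metric = mname, mean_g = mean(v), sd_g = sd_g,
                 ratio = sd_g / mean(v),
                 homogeneous = sd_g < 10 & sd_g / mean(v) < 0.15)
    }
  })
  do.call(rbind, rows)
}
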