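#' Construct a single-modality omics matrix
#'
#' Wraps a numeric samples x features matrix together with its modality name
#' and identifier vectors. All values must be finite; omics matrices with
#' missing entries must be cleaned (or samples dropped) upstream.
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param modality_name Single string naming the modality (e.g. `"mrna"`).
#' @param sample_ids Character vector of row identifiers; defaults to rownames.
#' @param feature_ids Character vector of column identifiers; defaults to
#'   colnames.
#' @param standardized Logical flag: have the columns been centred/scaled?
#' @param standardization_stats Optional list with per-feature `mean` and `sd`
#'   used for the transform (carried for serialization).
#'
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, modality_name, sample_ids = rownames(values),
                         feature_ids = colnames(values), standardized = FALSE,
                         standardization_stats = NULL) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(values)))
  if (nrow(values) != length(sample_ids)) {
    abort_("omics_matrix '", modality_name, "': ", nrow(values),
           " rows but ", length(sample_ids), " sample ids")
  }
  if (ncol(values) != length(feature_ids)) {
    abort_("omics_matrix '", modality_name, "': ", ncol(values),
           " columns but ", length(feature_ids), " feature ids")
  }
  if (anyDuplicated(sample_ids)) {
    abort_("omics_matrix '", modality_name, "': duplicate sample ids: ",
           paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    abort_("omics_matrix '", modality_name, "': non-finite value at row '",
           sample_ids[bad[1L]], "', column '", feature_ids[bad[2L]], "'")
  }
  rownames(values) <- sample_ids
  colnames(values) <- feature_ids
  structure(
    list(modality_name = modality_name, sample_ids = sample_ids,
         feature_ids = feature_ids, values = values,
         standardized = standardized,
         standardization_stats = standardization_stats),
    class = "omics_matrix"
  )
}

#' Construct an aligned multiomics dataset
#'
#' Bundles one [omics_matrix()] per modality with a per-sample class label.
#' All modalities must carry identical sample ids in identical order.
#'
#' @param modalities Named list of [omics_matrix()] objects (names are the
#'   modality names).
#' @param labels Factor (or character/integer coercible to factor) of length
#'   n_samples giving the class of each sample.
#' @param class_names Optional character vector fixing the class order; by
#'   default the factor levels of `labels`.
#'
#' @return An object of class `multiomics_dataset` with elements `modalities`,
#'   `labels` (factor) and `class_names`.
#' @export
multiomics_dataset <- function(modalities, labels, class_names = NULL) {
  if (length(modalities) < 1L) abort_("at least one modality is required")
  if (is.null(names(modalities)) || any(names(modalities) == "")) {
    names(modalities) <- vapply(modalities, `[[`, "", "modality_name")
  }
  ref_ids <- modalities[[1L]]$sample_ids
  for (m in modalities) {
    if (!identical(m$sample_ids, ref_ids)) {
      abort_("modality '", m$modality_name,
             "' sample ids differ from modality '",
             modalities[[1L]]$modality_name, "'")
    }
  }
  if (length(labels) != length(ref_ids)) {
    abort_("labels length ", length(labels), " != n_samples ", length(ref_ids))
  }
  if (is.null(class_names)) {
    labels <- as.factor(labels)
    class_names <- levels(labels)
  } else {
    if (!all(as.character(labels) %in% class_names)) {
      unknown <- setdiff(unique(as.character(labels)), class_names)
      abort_("labels contain classes not in class_names: ",
             paste(unknown, collapse = ", "))
    }
    labels <- factor(as.character(labels), levels = class_names)
  }
  if (anyNA(labels)) abort_("every sample must have exactly one label")
  structure(
    list(modalities = modalities, labels = labels, class_names = class_names),
    class = "multiomics_dataset"
  )
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat("<multiomics_dataset> ", n_samples(x), " samples, ",
      length(x$modalities), " modalities, ",
      length(x$class_names), " classes\n", sep = "")
  for (m in x$modalities) {
    cat("  ", m$modality_name, ": ", length(m$feature_ids), " features",
        if (m$standardized) " (standardized)" else "", "\n", sep = "")
  }
  invisible(x)
}

#' Number of samples in a multiomics dataset
#' @param dataset A `multiomics_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(dataset) length(dataset$labels)

#' Modality names of a multiomics dataset
#' @param dataset A `multiomics_dataset`.
#' @return Character vector of modality names.
#' @export
modality_names <- function(dataset) names(dataset$modalities)

#' Sample identifiers of a multiomics dataset
#' @param dataset A `multiomics_dataset`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(dataset) dataset$modalities[[1L]]$sample_ids

#' Subset a multiomics dataset by sample index
#'
#' @param dataset A `multiomics_dataset`.
#' @param idx Integer (or logical/character) index into the samples.
#' @return A `multiomics_dataset` restricted to (and reordered by) `idx`.
#' @export
subset_samples <- function(dataset, idx) {
  mods <- lapply(dataset$modalities, function(m) {
    omics_matrix(m$values[idx, , drop = FALSE], m$modality_name,
                 sample_ids = m$sample_ids[idx], feature_ids = m$feature_ids,
                 standardized = m$standardized,
                 standardization_stats = m$standardization_stats)
  })
  multiomics_dataset(mods, dataset$labels[idx],
                     class_names = dataset$class_names)
}

#' Read aligned multiomics matrices and labels from delimited text files
#'
#' Each matrix file must have a header row of feature ids and a first column
#' of sample ids. The label file is a two-column table (`sample_id,class`).
#' Samples present in **all** matrix files and in the label file are kept, in
#' label-file order; a message reports how many samples each file lost.
#'
#' @param matrix_paths Named character vector or list: modality name -> path.
#' @param label_path Path to the two-column label file (comma-separated by
#'   default).
#' @param sep Field separator of the matrix files (default tab).
#' @param label_sep Field separator of the label file (default comma).
#' @param class_names Optional character vector of allowed classes; a label
#'   outside this set is an error.
#'
#' @return A `multiomics_dataset`.
#' @export
read_multiomics <- function(matrix_paths, label_path, sep = "\t",
                            label_sep = ",", class_names = NULL) {
  matrix_paths <- as.list(matrix_paths)
  if (is.null(names(matrix_paths)) || any(names(matrix_paths) == "")) {
    abort_("matrix_paths must be a named list/vector: modality -> path")
  }
  lab <- utils::read.table(label_path, header = TRUE, sep = label_sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(lab) < 2L) abort_("label file must have two columns (sample_id, class)")
  lab_ids <- as.character(lab[[1L]])
  lab_cls <- as.character(lab[[2L]])
  if (anyDuplicated(lab_ids)) {
    abort_("duplicate sample id in label file: ",
           paste(unique(lab_ids[duplicated(lab_ids)]), collapse = ", "))
  }
  if (!is.null(class_names) && !all(lab_cls %in% class_names)) {
    abort_("label file contains classes not in class_names: ",
           paste(setdiff(unique(lab_cls), class_names), collapse = ", "))
  }

  raw <- list()
  for (nm in names(matrix_paths)) {
    path <- matrix_paths[[nm]]
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            row.names = NULL)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids)) {
      abort_("duplicate sample id in '", path, "': ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    vals <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(vals) <- "double"
    if (anyNA(vals) || any(!is.finite(vals))) {
      bad <- which(!is.finite(vals), arr.ind = TRUE)[1L, ]
      abort_("NaN/missing value in '", path, "' at row '", ids[bad[1L]],
             "', column '", colnames(vals)[bad[2L]], "'")
    }
    rownames(vals) <- ids
    raw[[nm]] <- vals
  }

  keep <- lab_ids
  for (nm in names(raw)) keep <- keep[keep %in% rownames(raw[[nm]])]
  if (length(keep) == 0L) {
    abort_("no sample id is shared by all matrix files and the label file")
  }
  for (nm in names(raw)) {
    dropped <- nrow(raw[[nm]]) - length(keep)
    message("read_multiomics: '", nm, "' dropped ", dropped,
            " sample(s) not shared by all files")
  }
  message("read_multiomics: label file dropped ",
          length(lab_ids) - length(keep), " sample(s) not shared by all files")

  mods <- lapply(names(raw), function(nm) {
    omics_matrix(raw[[nm]][keep, , drop = FALSE], nm, sample_ids = keep)
  })
  names(mods) <- names(raw)
  labels <- lab_cls[match(keep, lab_ids)]
  multiomics_dataset(mods, labels, class_names = class_names)
}

#' Standardize every modality to zero mean and unit variance
#'
#' Fits per-feature means and standard deviations (sample sd, denominator
#' n - 1) or applies previously fitted statistics (train-fitted stats applied
#' to validation/test data). Zero-variance features are mapped to all-zeros
#' (the sd is replaced by 1 internally) with a warning: real omics matrices
#' contain constant columns and dropping them silently would desynchronize
#' feature ids across splits.
#'
#' @param dataset A `multiomics_dataset`.
#' @param stats Optional statistics list returned by a previous call; when
#'   supplied, those statistics are applied instead of refitting.
#'
#' @return List with elements `dataset` (standardized copy) and `stats`
#'   (named per-modality list of `mean`, `sd`, `zero_var`).
#' @export
standardize_multiomics <- function(dataset, stats = NULL) {
  fit <- is.null(stats)
  if (fit) stats <- list()
  mods <- dataset$modalities
  for (nm in names(mods)) {
    m <- mods[[nm]]
    if (fit) {
      mu <- colMeans(m$values)
      sd_ <- apply(m$values, 2L, stats::sd)
      zero <- !is.finite(sd_) | sd_ <= .Machine$double.eps^0.5
      if (any(zero)) {
        warning("standardize_multiomics: modality '", nm, "' has ",
                sum(zero), " zero-variance feature(s); mapped to all-zeros",
                call. = FALSE)
        sd_[zero] <- 1
      }
      stats[[nm]] <- list(mean = mu, sd = sd_, zero_var = zero)
    }
    st <- stats[[nm]]
    if (is.null(st)) abort_("no standardization stats for modality '", nm, "'")
    vals <- sweep(sweep(m$values, 2L, st$mean, "-"), 2L, st$sd, "/")
    mods[[nm]] <- omics_matrix(vals, nm, sample_ids = m$sample_ids,
                               feature_ids = m$feature_ids,
                               standardized = TRUE,
                               standardization_stats = st)
  }
  dataset$modalities <- mods
  list(dataset = dataset, stats = stats)
}

# Largest-remainder allocation of n items to parts with the given ratios.
largest_remainder <- function(n, ratios) {
  quota <- n * ratios
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- quota - base
    take <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Splits a dataset into three partitions while preserving the proportion of
#' each class. Per-class allocation uses largest-remainder rounding of
#' `class_size * ratio`; within each class the samples are shuffled by `seed`
#' before allocation, and the sample order inside each partition is shuffled
#' as well. Deterministic given `seed`.
#'
#' @param dataset A `multiomics_dataset`; every class must have >= 3 samples.
#' @param ratios Numeric length-3 vector `(train, val, test)`, summing to 1.
#' @param seed Integer seed controlling the shuffles.
#'
#' @return Named list of three `multiomics_dataset`s: `train`, `val`, `test`.
#' @export
split_stratified <- function(dataset, ratios = c(0.70, 0.15, 0.15), seed = 1L) {
  if (length(ratios) != 3L || any(ratios < 0) ||
      abs(sum(ratios) - 1) > 1e-9) {
    abort_("ratios must be three non-negative numbers summing to 1")
  }
  y <- dataset$labels
  counts <- table(y)
  small <- names(counts)[counts < 3L]
  if (length(small) > 0L) {
    abort_("classes with fewer than 3 samples cannot be stratified: ",
           paste(small, collapse = ", "))
  }
  with_seed_(seed, {
    parts <- list(integer(0), integer(0), integer(0))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      alloc <- largest_remainder(length(idx), ratios)
      bounds <- cumsum(alloc)
      parts[[1L]] <- c(parts[[1L]], idx[seq_len(alloc[1L])])
      if (alloc[2L] > 0) {
        parts[[2L]] <- c(parts[[2L]], idx[(bounds[1L] + 1L):bounds[2L]])
      }
      if (alloc[3L] > 0) {
        parts[[3L]] <- c(parts[[3L]], idx[(bounds[2L] + 1L):bounds[3L]])
      }
    }
    parts <- lapply(parts, function(ix) ix[sample.int(length(ix))])
    list(train = subset_samples(dataset, parts[[1L]]),
         val = subset_samples(dataset, parts[[2L]]),
         test = subset_samples(dataset, parts[[3L]]))
  })
}

#' Subsample a dataset while preserving class proportions
#'
#' Retains `max(1, round(class_size * fraction))` samples per class (round
#' half away from zero), drawn uniformly at random within each class.
#' Deterministic given `seed`. This implements the training-subset protocol
#' of learning-curve experiments (1%, 2.5%, ... of the training set).
#'
#' @param dataset A `multiomics_dataset`.
#' @param fraction Fraction in (0, 1] of each class to retain.
#' @param seed Integer seed.
#'
#' @return A `multiomics_dataset` with the subsampled rows.
#' @export
subsample_fraction <- function(dataset, fraction, seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    abort_("fraction must be a single number in (0, 1]")
  }
  y <- dataset$labels
  with_seed_(seed, {
    keep <- integer(0)
    for (cl in levels(y)) {
      idx <- which(y == cl)
      n_keep <- max(1L, as.integer(floor(length(idx) * fraction + 0.5)))
      keep <- c(keep, idx[sample.int(length(idx), n_keep)])
    }
    subset_samples(dataset, sort(keep))
  })
}
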