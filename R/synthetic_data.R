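#' Specify a synthetic multiomics dataset with planted structure
#'
#' The generator emulates M aligned omics matrices with (i) class-dependent
#' mean shifts on a random feature subset of each modality (unimodal signal,
#' effect size `d`), (ii) a planted cross-modal interaction on designated
#' graph edges, and (iii) i.i.d. Gaussian noise. The interaction is built
#' through a per-sample latent factor `z ~ N(0, 1)` that loads with `+gamma`
#' on a random subset of source features and with class-signed `gamma`
#' (a scalar sign in {-1, 0, +1} per class) on a subset of target features:
#' each affected class is decodable from the sign of source x target feature
#' products, but neither modality alone carries the class in its marginal
#' means or within-modality covariance.
#'
#' @param n_samples Number of samples.
#' @param class_props Named numeric vector of class proportions (sums to 1);
#'   names are the class names.
#' @param modalities List of `list(name, p, d)` per modality: feature count
#'   `p >= 4` and unimodal effect size `d >= 0`.
#' @param planted_edges List of `list(source, target, gamma, class_signs)`;
#'   `class_signs` is a numeric vector (values in -1/0/+1) over the classes
#'   in `class_props` order. `gamma >= 0` is the interaction strength.
#' @param noise_sd Gaussian noise standard deviation.
#' @param frac_informative Fraction of each modality's features carrying each
#'   signal (floor of 4 features).
#' @param seed Integer seed; generation is deterministic given the spec.
#'
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples, class_props, modalities, planted_edges =
                             list(), noise_sd = 1.0, frac_informative = 0.1,
                           seed = 1L) {
  if (abs(sum(class_props) - 1) > 1e-9 || any(class_props <= 0)) {
    abort_("class_props must be positive and sum to 1")
  }
  if (is.null(names(class_props))) {
    names(class_props) <- paste0("class", seq_along(class_props))
  }
  for (m in modalities) {
    if (m$p < 4L) abort_("modality '", m$name, "': p must be >= 4")
    if ((m$d %||% 0) < 0) abort_("modality '", m$name, "': d must be >= 0")
  }
  mod_names <- vapply(modalities, `[[`, "", "name")
  C <- length(class_props)
  for (e in planted_edges) {
    if (!all(c(e$source, e$target) %in% mod_names)) {
      abort_("planted edge endpoints must be modality names")
    }
    if ((e$gamma %||% 0) < 0) abort_("gamma must be >= 0")
    if (!is.null(e$class_signs) && length(e$class_signs) != C) {
      abort_("class_signs must have one entry per class")
    }
  }
  structure(list(n_samples = n_samples, class_props = class_props,
                 modalities = modalities, planted_edges = planted_edges,
                 noise_sd = noise_sd, frac_informative = frac_informative,
                 seed = seed),
            class = "synthetic_spec")
}

#' Default desk-scale synthetic spec
#'
#' n = 600 samples, C = 4 balanced classes, M = 3 modalities (`cnv`, `mrna`,
#' `prot`) with 200 features each, weak unimodal effects (d = 0.25) and two
#' strong planted interactions (gamma = 2) on the chain edges of
#' [default_modality_graph()] (cnv -> mrna -> prot), with complementary
#' class-sign groupings (+,+,-,-) and (+,-,+,-): the four classes are jointly
#' decodable from the two interaction products but only weakly from any
#' single modality. Because the two edges share no target, every modality
#' carries at most one class-signed loading, so no within-modality covariance
#' betrays the class.
#'
#' @param seed Integer seed.
#' @param n_samples,d,gamma Override the scale, unimodal effect size and
#'   interaction strength.
#' @return A `synthetic_spec`.
#' @export
default_synthetic_spec <- function(seed = 1L, n_samples = 600L, d = 0.25,
                                   gamma = 2.0) {
  synthetic_spec(
    n_samples = n_samples,
    class_props = c(c1 = 0.25, c2 = 0.25, c3 = 0.25, c4 = 0.25),
    modalities = list(list(name = "cnv", p = 200L, d = d),
                      list(name = "mrna", p = 200L, d = d),
                      list(name = "prot", p = 200L, d = d)),
    planted_edges = list(
      list(source = "cnv", target = "mrna", gamma = gamma,
           class_signs = c(1, 1, -1, -1)),
      list(source = "mrna", target = "prot", gamma = gamma,
           class_signs = c(1, -1, 1, -1))
    ),
    noise_sd = 1.0, seed = seed
  )
}

#' Generate a synthetic multiomics dataset from a spec
#'
#' Class counts follow largest-remainder rounding of the proportions, so a
#' balanced spec yields exactly balanced classes. Deterministic given the
#' spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (a `multiomics_dataset`) and `truth` (a list
#'   recording the class assignment, per-class informative feature sets, and
#'   per-edge planted feature sets and class signs).
#' @export
generate_multiomics <- function(spec) {
  n <- spec$n_samples
  cls <- names(spec$class_props)
  C <- length(cls)
  counts <- largest_remainder(n, spec$class_props)
  with_seed_(spec$seed, {
    y <- sample(rep.int(seq_len(C), counts))
    ids <- sprintf("sample_%04d", seq_len(n))
    X <- list()
    truth <- list(classes = stats::setNames(as.list(counts), cls),
                  unimodal = list(), planted = list())
    for (m in spec$modalities) {
      p <- m$p
      n_inf <- max(4L, as.integer(floor(p * spec$frac_informative + 0.5)))
      vals <- matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
      uni <- list()
      for (c in seq_len(C)) {
        feats <- sample.int(p, n_inf)
        signs <- sample(c(-1, 1), n_inf, replace = TRUE)
        vals[y == c, feats] <- sweep(vals[y == c, feats, drop = FALSE], 2L,
                                     (m$d %||% 0) * signs, "+")
        uni[[cls[c]]] <- list(features = feats, signs = signs)
      }
      colnames(vals) <- sprintf("%s_f%03d", m$name, seq_len(p))
      rownames(vals) <- ids
      X[[m$name]] <- vals
      truth$unimodal[[m$name]] <- uni
    }
    for (e in spec$planted_edges) {
      gamma <- e$gamma %||% 0
      signs <- e$class_signs %||% rep(c(1, -1), length.out = C)
      p_src <- ncol(X[[e$source]])
      p_tgt <- ncol(X[[e$target]])
      m_src <- max(4L, as.integer(floor(p_src * spec$frac_informative + 0.5)))
      m_tgt <- max(4L, as.integer(floor(p_tgt * spec$frac_informative + 0.5)))
      f_src <- sample.int(p_src, m_src)
      f_tgt <- sample.int(p_tgt, m_tgt)
      z <- stats::rnorm(n)
      X[[e$source]][, f_src] <- X[[e$source]][, f_src] + gamma * z
      X[[e$target]][, f_tgt] <- X[[e$target]][, f_tgt] +
        (signs[y] * gamma * z)
      truth$planted[[paste(e$source, e$target, sep = "->")]] <- list(
        source = e$source, target = e$target, gamma = gamma,
        class_signs = stats::setNames(as.list(signs), cls),
        source_features = f_src, target_features = f_tgt)
    }
    mods <- lapply(names(X), function(nm) omics_matrix(X[[nm]], nm))
    names(mods) <- names(X)
    dataset <- multiomics_dataset(mods, factor(cls[y], levels = cls),
                                  class_names = cls)
    list(dataset = dataset, truth = truth)
  })
}

#' Export a multiomics dataset to delimited text files
#'
#' Writes one TSV per modality (samples x features, header + index column), a
#' two-column `labels.csv`, optionally a `ground_truth.json` and a
#' `graph.yaml`, all loadable by [read_multiomics()] /
#' [read_modality_graph()]. Files are staged in a temporary directory and
#' moved into place, so a failure leaves no partial output.
#'
#' @param dataset A `multiomics_dataset`.
#' @param dir Output directory (created if needed).
#' @param truth Optional ground-truth list (from [generate_multiomics()]).
#' @param graph Optional `modality_graph` to serialize alongside.
#' @return Named character vector of the files written, invisibly.
#' @export
export_multiomics <- function(dataset, dir, truth = NULL, graph = NULL) {
  parent <- dirname(normalizePath(dir, mustWork = FALSE))
  if (!dir.exists(parent) || file.access(parent, 2L) != 0L) {
    abort_("cannot write to '", dir, "': parent directory not writable")
  }
  stage <- tempfile("export_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  files <- character()
  for (m in dataset$modalities) {
    f <- file.path(stage, paste0(m$modality_name, ".tsv"))
    # 17 significant digits so the text round-trips doubles exactly
    chr <- matrix(sprintf("%.17g", m$values), nrow(m$values),
                  dimnames = dimnames(m$values))
    df <- data.frame(sample_id = m$sample_ids, chr, check.names = FALSE)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files[m$modality_name] <- paste0(m$modality_name, ".tsv")
  }
  utils::write.table(
    data.frame(sample_id = sample_ids(dataset),
               class = as.character(dataset$labels)),
    file.path(stage, "labels.csv"), sep = ",", quote = FALSE,
    row.names = FALSE)
  files["labels"] <- "labels.csv"
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(stage, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    files["ground_truth"] <- "ground_truth.json"
  }
  if (!is.null(graph)) {
    write_modality_graph(graph, file.path(stage, "graph.yaml"))
    files["graph"] <- "graph.yaml"
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ok <- file.copy(file.path(stage, files), dir, overwrite = TRUE)
  if (!all(ok)) abort_("failed to move exported files into '", dir, "'")
  invisible(stats::setNames(file.path(dir, files), names(files)))
}
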