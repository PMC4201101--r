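#' Specification of a synthetic multimodal dataset
#'
#' Describes a synthetic cohort with the feature structure typical of
#' multimodal Alzheimer's studies: two continuous imaging blocks (regional
#' MRI volumes and PET intensities), a small CSF biomarker block, and a SNP
#' genotype block coded as minor-allele counts in \{0, 1, 2\}.  Subjects
#' carry one of three ordered diagnostic labels (HC < MCI < AD) and a sparse
#' subset of features in each modality carries a linear mean trend along
#' that progression.
#'
#' Defaults mirror a 189-subject cohort (47 HC, 93 MCI, 49 AD) with
#' 93 + 93 + 3 + 189 features.  Effect sizes are standardized mean shifts
#' per class step (Cohen's-d-like, in units of `noise_sd`); the defaults
#' encode the qualitative modality ordering PET > MRI > CSF > SNP that such
#' cohorts exhibit, with deliberately weak SNP signal.
#'
#' @param n_per_class named integer vector of subject counts for the ordered
#'   classes `c(HC, MCI, AD)`.
#' @param modality_dims named integer vector of feature counts per modality,
#'   in canonical order MRI, PET, CSF, SNP.
#' @param informative_counts named integer vector: how many features of each
#'   modality carry class signal.  Must not exceed `modality_dims`.
#' @param effect_sizes named numeric vector: standardized mean shift per
#'   class step for informative features (unitless).
#' @param snp_maf_range length-2 numeric in (0, 0.5]: per-SNP minor allele
#'   frequencies are drawn uniformly from this interval.
#' @param noise_sd residual standard deviation of the continuous blocks.
#' @param seed integer master seed; the same spec and seed always generate a
#'   bit-identical dataset.
#' @return An object of class `synth_spec`.
#' @seealso [generate_multimodal()]
#' @export
synth_spec <- function(n_per_class = c(HC = 47, MCI = 93, AD = 49),
                       modality_dims = c(MRI = 93, PET = 93, CSF = 3, SNP = 189),
                       informative_counts = c(MRI = 10, PET = 10, CSF = 2, SNP = 10),
                       effect_sizes = c(MRI = 0.8, PET = 1.0, CSF = 0.7, SNP = 0.3),
                       snp_maf_range = c(0.1, 0.5),
                       noise_sd = 1,
                       seed = 1L) {
  if (length(n_per_class) != 3L) stop("n_per_class must have 3 entries (HC, MCI, AD)")
  if (is.null(names(n_per_class))) names(n_per_class) <- c("HC", "MCI", "AD")
  mods <- names(modality_dims)
  if (is.null(mods) || any(!nzchar(mods))) stop("modality_dims must be named")
  informative_counts <- informative_counts[mods]
  effect_sizes <- effect_sizes[mods]
  if (any(is.na(informative_counts)) || any(is.na(effect_sizes)))
    stop("informative_counts and effect_sizes must cover every modality")
  names(informative_counts) <- names(effect_sizes) <- mods
  if (any(n_per_class < 0) || any(modality_dims <= 0) || any(informative_counts < 0))
    stop("counts must be non-negative and dimensions positive")
  if (any(n_per_class == 0)) stop("every class must contain at least one subject")
  if (any(informative_counts > modality_dims))
    stop("informative_counts may not exceed modality_dims")
  if (length(snp_maf_range) != 2L || snp_maf_range[1] <= 0 ||
      snp_maf_range[2] > 0.5 || snp_maf_range[1] > snp_maf_range[2])
    stop("snp_maf_range must lie within (0, 0.5]")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(
    n_per_class = stats::setNames(as.integer(n_per_class), c("HC", "MCI", "AD")),
    modality_dims = stats::setNames(as.integer(modality_dims), mods),
    informative_counts = stats::setNames(as.integer(informative_counts), mods),
    effect_sizes = effect_sizes,
    snp_maf_range = snp_maf_range,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat("Synthetic multimodal cohort spec\n")
  cat("  subjects:", paste(sprintf("%s=%d", names(x$n_per_class), x$n_per_class),
                           collapse = ", "), "\n")
  cat("  modalities:", paste(sprintf("%s(%d, %d informative, effect %.2f)",
                                     names(x$modality_dims), x$modality_dims,
                                     x$informative_counts, x$effect_sizes),
                             collapse = "; "), "\n")
  cat("  SNP MAF range: [", x$snp_maf_range[1], ", ", x$snp_maf_range[2],
      "]; noise sd ", x$noise_sd, "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

class_levels <- function() c("HC", "MCI", "AD")

is_snp_modality <- function(name) toupper(name) == "SNP"

#' Generate a synthetic multimodal dataset
#'
#' Draws a cohort according to a [synth_spec()].  Continuous modalities are
#' class-mean-shifted Gaussians: an informative feature of modality `m` has
#' mean `c * effect_sizes[m] * noise_sd` for class index
#' `c = 0, 1, 2` (HC, MCI, AD) and standard deviation `noise_sd`;
#' non-informative features are pure noise.  SNP genotypes are
#' `Binomial(2, p)` counts whose per-SNP allele frequency is shifted
#' additively on the logit scale by `c * effect_sizes["SNP"]` for
#' informative SNPs, which keeps genotypes on the \{0,1,2\} support for any
#' effect size.  The planted informative index sets are recorded as ground
#' truth for selector benchmarking.
#'
#' @param spec a [synth_spec()].
#' @return An object of class `multimodal_dataset`: a list with `blocks`
#'   (named list of subjects x features matrices), `labels` (factor with
#'   levels HC < MCI < AD), `subject_ids`, `informative_truth` (named list
#'   of planted column indices) and the generating `spec`.
#' @examples
#' ds <- generate_multimodal(synth_spec(seed = 7))
#' table(ds$labels)
#' @export
generate_multimodal <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- sum(spec$n_per_class)
  labels <- factor(rep(class_levels(), times = spec$n_per_class),
                   levels = class_levels())
  cls_idx <- as.integer(labels) - 1L  # 0, 1, 2 along the progression
  subject_ids <- sprintf("S%04d", seq_len(n))
  mods <- names(spec$modality_dims)
  seeds <- derive_seeds(spec$seed, length(mods))
  blocks <- list()
  truth <- list()
  snp_maf <- list()
  for (mi in seq_along(mods)) {
    m <- mods[mi]
    d <- spec$modality_dims[[m]]
    k <- spec$informative_counts[[m]]
    eff <- spec$effect_sizes[[m]]
    blocks[[m]] <- with_seed(seeds[mi], {
      info <- if (k > 0) sort(sample.int(d, k)) else integer(0)
      truth[[m]] <- info
      if (is_snp_modality(m)) {
        maf <- stats::runif(d, spec$snp_maf_range[1], spec$snp_maf_range[2])
        snp_maf[[m]] <- maf
        shift <- matrix(0, n, d)
        if (length(info)) shift[, info] <- outer(cls_idx, rep(eff, length(info)))
        p <- stats::plogis(matrix(stats::qlogis(maf), n, d, byrow = TRUE) + shift)
        g <- matrix(stats::rbinom(n * d, 2L, as.vector(p)), n, d)
        storage.mode(g) <- "double"
        g
      } else {
        mu <- matrix(0, n, d)
        if (length(info)) mu[, info] <- outer(cls_idx, rep(eff * spec$noise_sd, length(info)))
        mu + matrix(stats::rnorm(n * d, sd = spec$noise_sd), n, d)
      }
    })
    colnames(blocks[[m]]) <- sprintf("%s_%0*d", m, max(3L, nchar(d)), seq_len(d))
    rownames(blocks[[m]]) <- subject_ids
  }
  ds <- structure(list(
    blocks = blocks,
    labels = labels,
    subject_ids = subject_ids,
    informative_truth = truth,
    snp_maf = if (length(snp_maf)) snp_maf else NULL,
    spec = spec
  ), class = "multimodal_dataset")
  validate_dataset(ds)
  ds
}

validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "multimodal_dataset"))
  n <- length(ds$labels)
  if (n == 0L) stop("dataset has no subjects")
  if (anyDuplicated(ds$subject_ids)) stop("subject ids must be unique")
  if (length(ds$subject_ids) != n) stop("subject_ids and labels differ in length")
  if (!all(levels(ds$labels) == class_levels()))
    stop("labels must use levels ", paste(class_levels(), collapse = ", "))
  for (m in names(ds$blocks)) {
    b <- ds$blocks[[m]]
    if (nrow(b) != n) stop("block ", m, " row count does not match label count")
    if (is_snp_modality(m) && !all(b %in% c(0, 1, 2)))
      stop("SNP block entries must be in {0, 1, 2}")
  }
  invisible(ds)
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  cat("Multimodal dataset:", length(x$labels), "subjects\n")
  cat("  labels:", paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                         collapse = ", "), "\n")
  for (m in names(x$blocks))
    cat(sprintf("  %s: %d features\n", m, ncol(x$blocks[[m]])))
  invisible(x)
}

#' Write / read a multimodal dataset as delimited text
#'
#' One CSV per modality (first column the subject id, header row the feature
#' names), a labels CSV, and a JSON sidecar holding the generating spec and
#' the planted ground-truth indices when present.  The round trip is
#' lossless for values, labels and modality order.
#'
#' @param ds a `multimodal_dataset`.
#' @param path directory to create/populate.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   the reconstructed `multimodal_dataset`.
#' @export
write_dataset <- function(ds, path) {
  validate_dataset(ds)
  if (length(ds$labels) == 0L) stop("refusing to write a dataset with 0 subjects")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (m in names(ds$blocks)) {
    df <- data.frame(subject_id = ds$subject_ids, ds$blocks[[m]],
                     check.names = FALSE)
    utils::write.csv(df, file.path(path, paste0(m, ".csv")), row.names = FALSE)
  }
  utils::write.csv(data.frame(subject_id = ds$subject_ids,
                              label = as.character(ds$labels)),
                   file.path(path, "labels.csv"), row.names = FALSE)
  sidecar <- list(modalities = names(ds$blocks))
  # named atomic vectors lose their names as JSON arrays; store them as
  # named lists so the round trip is lossless
  if (!is.null(ds$spec)) sidecar$spec <- lapply(unclass(ds$spec), as.list)
  if (!is.null(ds$informative_truth)) sidecar$informative_truth <- ds$informative_truth
  jsonlite::write_json(sidecar, file.path(path, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  side <- jsonlite::read_json(file.path(path, "dataset.json"), simplifyVector = TRUE)
  mods <- side$modalities
  lab <- utils::read.csv(file.path(path, "labels.csv"), stringsAsFactors = FALSE)
  if (!all(lab$label %in% class_levels()))
    stop("unknown label level: ", paste(setdiff(lab$label, class_levels()), collapse = ", "))
  blocks <- list()
  for (m in mods) {
    df <- utils::read.csv(file.path(path, paste0(m, ".csv")), check.names = FALSE)
    if (!identical(df$subject_id, lab$subject_id))
      stop("subject ids of block ", m, " do not match the label file")
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- df$subject_id
    blocks[[m]] <- mat
  }
  spec <- NULL
  if (!is.null(side$spec)) {
    spec <- side$spec
    spec$n_per_class <- unlist(spec$n_per_class)
    spec$modality_dims <- unlist(spec$modality_dims)
    spec$informative_counts <- unlist(spec$informative_counts)
    spec$effect_sizes <- unlist(spec$effect_sizes)
    spec$snp_maf_range <- unlist(spec$snp_maf_range)
    spec <- do.call(synth_spec, spec)
  }
  truth <- NULL
  if (!is.null(side$informative_truth))
    truth <- lapply(side$informative_truth, as.integer)
  ds <- structure(list(
    blocks = blocks,
    labels = factor(lab$label, levels = class_levels()),
    subject_ids = lab$subject_id,
    informative_truth = truth,
    spec = spec
  ), class = "multimodal_dataset")
  validate_dataset(ds)
  ds
}
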