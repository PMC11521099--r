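#' Synthetic brain-phantom cohort specification
#'
#' Describes a two-class cohort of brain-like 3D phantoms: an ellipsoidal
#' "brain" of moderate tissue intensity on a zero background, containing
#' `n_regions` interior ellipsoidal regions at `base_intensity`. Roughly half
#' of the regions (the "designated" ones, mimicking cortical areas that carry
#' a diagnostic signal) gain `effect_size` in mean intensity for class-1
#' subjects. i.i.d. Gaussian noise with `noise_sd` is added voxelwise.
#'
#' Region placement is a deterministic function of `seed` alone, so the
#' class effect sits at the same anatomical location for every subject in a
#' cohort; per-subject noise streams are derived from `(seed, label,
#' draw_index)` so generation is fully reproducible with no global RNG state.
#'
#' @param shape integer length-3 volume shape; default 32^3 (128^3 is
#'   supported but slow on a single CPU).
#' @param n_regions number of interior regions.
#' @param base_intensity mean intensity of interior regions before any class
#'   effect (background is 0, non-region brain tissue is
#'   `0.5 * base_intensity`).
#' @param effect_size intensity added to designated regions for label-1
#'   subjects; 0 makes the two class distributions identical.
#' @param noise_sd standard deviation of additive Gaussian noise; 0 makes
#'   generation deterministic given `(spec, label, draw_index)`.
#' @param seed integer master seed for layout and all noise streams.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 32, 32), n_regions = 5,
                         base_intensity = 1, effect_size = 0.5,
                         noise_sd = 0.05, seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("`shape` must be 3 positive integers", call. = FALSE)
  }
  if (n_regions < 1L) stop("`n_regions` must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(shape = shape, n_regions = as.integer(n_regions),
                 base_intensity = base_intensity, effect_size = effect_size,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> %s, %d regions, base %.3g, ",
                     "effect %.3g, noise sd %.3g, seed %d\n"),
              paste(x$shape, collapse = "x"), x$n_regions, x$base_intensity,
              x$effect_size, x$noise_sd, x$seed))
  invisible(x)
}

# run `expr` under a private RNG stream without touching the caller's state
with_private_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# deterministic region layout: masks depend on spec$seed only
phantom_layout <- function(spec) {
  d <- spec$shape
  cx <- (seq_len(d[1]) - (d[1] + 1) / 2) / (d[1] / 2)
  cy <- (seq_len(d[2]) - (d[2] + 1) / 2) / (d[2] / 2)
  cz <- (seq_len(d[3]) - (d[3] + 1) / 2) / (d[3] / 2)
  # normalized coordinates in [-1, 1] per axis
  X <- array(rep(cx, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(cy, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(cz, each = d[1] * d[2]), dim = d)
  brain <- (X / 0.9)^2 + (Y / 0.9)^2 + (Z / 0.9)^2 <= 1
  centers <- with_private_seed(spec$seed, {
    matrix(stats::runif(3L * spec$n_regions, -0.45, 0.45),
           ncol = 3L, byrow = TRUE)
  })
  radii <- with_private_seed(spec$seed + 1L, {
    matrix(stats::runif(3L * spec$n_regions, 0.12, 0.22),
           ncol = 3L, byrow = TRUE)
  })
  regions <- lapply(seq_len(spec$n_regions), function(r) {
    ((X - centers[r, 1]) / radii[r, 1])^2 +
      ((Y - centers[r, 2]) / radii[r, 2])^2 +
      ((Z - centers[r, 3]) / radii[r, 3])^2 <= 1
  })
  designated <- seq_len(max(1L, ceiling(spec$n_regions / 2)))
  list(brain = brain, regions = regions, designated = designated)
}

#' Generate one phantom volume
#'
#' @param spec a [phantom_spec()].
#' @param label class label, 0 (healthy-like) or 1 (disease-like).
#' @param draw_index 1-based subject index within the class; distinct values
#'   yield independent noise draws.
#' @return A raw-intensity `mri_volume`.
#' @export
generate_phantom <- function(spec, label, draw_index = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!label %in% c(0, 1)) stop("`label` must be 0 or 1", call. = FALSE)
  lay <- phantom_layout(spec)
  a <- array(0, dim = spec$shape)
  a[lay$brain] <- 0.5 * spec$base_intensity
  for (r in seq_along(lay$regions)) a[lay$regions[[r]]] <- spec$base_intensity
  if (label == 1 && spec$effect_size != 0) {
    for (r in lay$designated) {
      a[lay$regions[[r]]] <- a[lay$regions[[r]]] + spec$effect_size
    }
  }
  if (spec$noise_sd > 0) {
    noise_seed <- (spec$seed + 1000003 * (label + 1) + 7919 * draw_index) %%
      2147483647
    a <- a + with_private_seed(noise_seed, {
      array(stats::rnorm(length(a), sd = spec$noise_sd), dim = spec$shape)
    })
  }
  as_volume(a)
}

#' Region masks of a phantom layout
#'
#' Returns the logical masks implied by a spec: the brain ellipsoid, each
#' interior region and the union of designated (class-effect) regions.
#' Useful for checking where a difference map localizes.
#'
#' @param spec a [phantom_spec()].
#' @return list with `brain`, `regions` (list) and `designated_mask`.
#' @export
phantom_masks <- function(spec) {
  lay <- phantom_layout(spec)
  dm <- Reduce(`|`, lay$regions[lay$designated])
  list(brain = lay$brain, regions = lay$regions, designated_mask = dm)
}

#' Generate a balanced labeled cohort
#'
#' @param spec a [phantom_spec()].
#' @param n_per_class subjects per class (>= 1).
#' @return A `labeled_cohort`: list with `volumes` (length `2 * n_per_class`)
#'   and integer `labels` (0 = healthy-like, 1 = disease-like).
#' @export
generate_cohort <- function(spec, n_per_class) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_per_class < 1L) stop("`n_per_class` must be >= 1", call. = FALSE)
  labels <- rep(c(0L, 1L), each = n_per_class)
  volumes <- lapply(seq_along(labels), function(i) {
    generate_phantom(spec, labels[i], draw_index = ((i - 1L) %% n_per_class) + 1L)
  })
  as_cohort(volumes, labels)
}

#' Construct a labeled cohort from volumes and labels
#'
#' @param volumes list of `mri_volume` objects.
#' @param labels integer vector of 0/1 labels, same length.
#' @return A `labeled_cohort`.
#' @export
as_cohort <- function(volumes, labels) {
  labels <- as.integer(labels)
  if (length(volumes) != length(labels)) {
    stop("`volumes` and `labels` must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  structure(list(volumes = volumes, labels = labels),
            class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat(sprintf("<labeled_cohort> %d volumes (%d healthy, %d diseased)\n",
              length(x$labels), sum(x$labels == 0L), sum(x$labels == 1L)))
  invisible(x)
}

#' Apply a function over every volume of a cohort
#'
#' @param cohort a `labeled_cohort`.
#' @param f function taking and returning a `mri_volume`.
#' @return A `labeled_cohort` with transformed volumes, same labels.
#' @export
cohort_map <- function(cohort, f) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  as_cohort(lapply(cohort$volumes, f), cohort$labels)
}

#' Write a cohort to disk as NIfTI files plus a CSV manifest
#'
#' @param cohort a `labeled_cohort`.
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = "phantom") {
  stopifnot(inherits(cohort, "labeled_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(cohort$labels)
  files <- sprintf("%s_%03d.nii.gz", prefix, seq_len(n))
  for (i in seq_len(n)) {
    write_volume(cohort$volumes[[i]], file.path(dir, files[i]))
  }
  manifest <- data.frame(
    file = files, label = cohort$labels,
    class = ifelse(cohort$labels == 1L, "ASD", "HC"))
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing NIfTI files and `manifest.csv`.
#' @return A `labeled_cohort`.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir, call. = FALSE)
  manifest <- utils::read.csv(mpath)
  vols <- lapply(file.path(dir, manifest$file), read_volume)
  as_cohort(vols, manifest$label)
}
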