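#' Pipeline configuration
#'
#' Single configuration object for the full segmentation pipeline. Defaults
#' reproduce the method's standard settings: `beta = 0.5`, second-order
#' (8-connected) neighbourhood, `K = 3` pre-segmentation clusters, a
#' 3-component mixture for the stopping map, and unit weights
#' `lambda1 = lambda2 = mu = nu = 1`.
#'
#' @param window Optional `(low, high)` intensity window for normalization
#'   (default: observed min/max).
#' @param kmeans_K,kmeans_seed,kmeans_restarts Pre-segmentation K-means
#'   settings.
#' @param stats_method `"em"` or `"moment"` for [estimate_class_stats()].
#' @param beta,neighbourhood Potts prior settings (see [mrf_config()]).
#' @param icm_passes ICM refinement sweeps before freezing the energy map.
#' @param energy_assembly `"contrast"` or `"assigned"` (see
#'   [mrf_energy_map()]).
#' @param energy_normalize Min-max rescale the energy map to [0, 1].
#' @param region_feature `"mrf_energy"` (default) or `"intensity"` (ablation:
#'   a Chan-Vese-style region term on raw normalized intensity).
#' @param boundary `"bayes"` (default) or `"none"` (ablation: `S` identically
#'   1, i.e. an unweighted length term).
#' @param gmm_K,gmm_seed,gmm_tol,gmm_max_iter Mixture settings for the
#'   stopping map.
#' @param nodule_component,background_component Mixture component indices for
#'   [stopping_map()]; `NULL` (default) matches components to the two MRF
#'   class means automatically.
#' @param init_mode `"kmeans_mask"` or `"bayes_mask"` (see [init_phi()]).
#' @param lambda1,lambda2,mu,nu,epsilon,dt,max_iter,conv_tol Contour
#'   evolution settings (see [acm_config()]).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(window = NULL,
                            kmeans_K = 3L, kmeans_seed = 42L,
                            kmeans_restarts = 5L,
                            stats_method = "em",
                            beta = 0.5, neighbourhood = 8L,
                            icm_passes = 1L,
                            energy_assembly = "contrast",
                            energy_normalize = TRUE,
                            region_feature = "mrf_energy",
                            boundary = "bayes",
                            gmm_K = 3L, gmm_seed = 42L, gmm_tol = 1e-6,
                            gmm_max_iter = 500L,
                            nodule_component = NULL,
                            background_component = NULL,
                            init_mode = "kmeans_mask",
                            lambda1 = 1, lambda2 = 1, mu = 1, nu = 1,
                            epsilon = 1, dt = 0.1, max_iter = 500L,
                            conv_tol = 1e-4) {
  region_feature <- match.arg(region_feature, c("mrf_energy", "intensity"))
  boundary <- match.arg(boundary, c("bayes", "none"))
  stats_method <- match.arg(stats_method, c("em", "moment"))
  init_mode <- match.arg(init_mode, c("kmeans_mask", "bayes_mask"))
  cfg <- list(window = window, kmeans_K = as.integer(kmeans_K),
              kmeans_seed = as.integer(kmeans_seed),
              kmeans_restarts = as.integer(kmeans_restarts),
              stats_method = stats_method, beta = beta,
              neighbourhood = as.integer(neighbourhood),
              icm_passes = as.integer(icm_passes),
              energy_assembly = energy_assembly,
              energy_normalize = isTRUE(energy_normalize),
              region_feature = region_feature, boundary = boundary,
              gmm_K = as.integer(gmm_K), gmm_seed = as.integer(gmm_seed),
              gmm_tol = gmm_tol, gmm_max_iter = as.integer(gmm_max_iter),
              nodule_component = nodule_component,
              background_component = background_component,
              init_mode = init_mode,
              lambda1 = lambda1, lambda2 = lambda2, mu = mu, nu = nu,
              epsilon = epsilon, dt = dt, max_iter = as.integer(max_iter),
              conv_tol = conv_tol)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg A [pipeline_config()].
#' @return `read_pipeline_config()` returns a [pipeline_config()];
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Segment a GGO nodule
#'
#' Runs the full integrated active contour pipeline on a single image:
#' normalize, K-means pre-segmentation (K = 3), reduction to the two MRF
#' classes, Gaussian class statistics by EM, one-shot MRF energy map,
#' mixture fit and Bayesian probability-difference stopping map, level-set
#' initialization from the pre-segmentation, and contour evolution under the
#' integrated energy. Deterministic given the configuration.
#'
#' @param img An [intensity_image()] (or matrix of raw intensities).
#' @param cfg A [pipeline_config()].
#' @param roi Optional [roi()] to crop before segmenting; the result mask is
#'   in ROI coordinates with the offset recorded.
#' @return An object of class `segmentation_result`: list with `mask`,
#'   `phi`, `trace`, `iterations`, `converged`, `intermediates` (labels,
#'   class stats, energy map, mixture, stopping map, initial phi) and
#'   `config`.
#' @export
segment_nodule <- function(img, cfg = pipeline_config(), roi = NULL) {
  if (!inherits(img, "intensity_image")) img <- intensity_image(img)
  if (!is.null(roi)) img <- run_stage("crop", crop_image(img, roi))
  norm <- run_stage("normalize", normalize_image(img, cfg$window))
  labels3 <- run_stage("presegment",
    kmeans_presegment(norm, K = cfg$kmeans_K, seed = cfg$kmeans_seed,
                      n_restarts = cfg$kmeans_restarts))
  labels2 <- run_stage("reduce", reduce_to_two_classes(labels3, norm))
  stats <- run_stage("class_stats",
    estimate_class_stats(norm, labels2, method = cfg$stats_method))
  mcfg <- mrf_config(beta = cfg$beta, neighbourhood = cfg$neighbourhood)
  u <- if (cfg$region_feature == "mrf_energy") {
    run_stage("mrf_energy",
      mrf_energy_map(norm, labels2, stats, mcfg,
                     icm_passes = cfg$icm_passes,
                     normalize = cfg$energy_normalize,
                     assembly = cfg$energy_assembly))
  } else {
    energy_map(norm$pixels, normalized01 = TRUE)
  }
  theta <- NULL; post <- NULL; comps <- NULL
  S <- if (cfg$boundary == "bayes") {
    theta <- run_stage("gmm",
      fit_gmm_em(norm, K = cfg$gmm_K, seed = cfg$gmm_seed,
                 tol = cfg$gmm_tol, max_iter = cfg$gmm_max_iter))
    post <- run_stage("posterior", posterior_map(norm, theta))
    comps <- if (!is.null(cfg$nodule_component) &&
                 !is.null(cfg$background_component)) {
      list(nodule_k = cfg$nodule_component,
           background_k = cfg$background_component)
    } else {
      select_components(theta, stats)
    }
    run_stage("stopping_map",
              stopping_map(post, comps$nodule_k, comps$background_k))
  } else {
    matrix(1, nrow(norm$pixels), ncol(norm$pixels))
  }
  phi0 <- run_stage("init_phi",
    init_phi(labels2 = labels2, post = post,
             nodule_k = if (!is.null(comps)) comps$nodule_k else 2L,
             mode = cfg$init_mode))
  acm <- acm_config(lambda1 = cfg$lambda1, lambda2 = cfg$lambda2,
                    mu = cfg$mu, nu = cfg$nu, epsilon = cfg$epsilon,
                    dt = cfg$dt, max_iter = cfg$max_iter,
                    conv_tol = cfg$conv_tol)
  ev <- run_stage("evolve", evolve_contour(phi0, u, S, acm))
  structure(list(mask = ev$mask, phi = ev$phi, trace = ev$trace,
                 iterations = ev$iterations, converged = ev$converged,
                 intermediates = list(normalized = norm, labels3 = labels3,
                                      labels2 = labels2, stats = stats,
                                      energy = u, theta = theta,
                                      stopping = S, components = comps,
                                      phi0 = phi0),
                 config = cfg, roi = roi),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(paste0("<segmentation_result %d x %d, %d foreground px, ",
                     "%d iterations%s>\n"),
              nrow(x$mask), ncol(x$mask), sum(unclass(x$mask)),
              x$iterations, if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Segment a batch of images
#'
#' @param paths Character vector of image paths.
#' @param cfg A [pipeline_config()].
#' @param truth_paths Optional character vector of gold-standard mask PNGs
#'   (same length as `paths`); when given, IOU is reported per image.
#' @param out_dir Optional directory: predicted masks and a `summary.csv`
#'   (per-image rows plus a mean row) are written there.
#' @return A `data.frame` with one row per image (columns `path`, `iou`,
#'   `iterations`, `converged`, `error`); per-file failures are recorded and
#'   the batch continues.
#' @export
segment_batch <- function(paths, cfg = pipeline_config(),
                          truth_paths = NULL, out_dir = NULL) {
  n <- length(paths)
  res <- data.frame(path = as.character(paths), iou = rep(NA_real_, n),
                    iterations = rep(NA_integer_, n),
                    converged = rep(NA, n), error = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  for (i in seq_len(n)) {
    ok <- tryCatch({
      sr <- segment_nodule(read_image(paths[i]), cfg)
      res$iterations[i] <- sr$iterations
      res$converged[i] <- sr$converged
      if (!is.null(truth_paths)) {
        res$iou[i] <- iou(sr$mask, read_mask(truth_paths[i]))
      }
      if (!is.null(out_dir)) {
        write_mask(sr$mask, file.path(out_dir, paste0(
          tools::file_path_sans_ext(basename(paths[i])), "_mask.png")))
      }
      TRUE
    }, error = function(e) {
      res$error[i] <<- conditionMessage(e)
      FALSE
    })
    if (!ok) next
  }
  if (!is.null(out_dir)) {
    out <- res
    if (!is.null(truth_paths)) {
      out <- rbind(out, data.frame(path = "mean",
                                   iou = mean(res$iou, na.rm = TRUE),
                                   iterations = NA_integer_, converged = NA,
                                   error = NA_character_))
    }
    utils::write.csv(out, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  res
}

#' Run the phantom benchmark suite
#'
#' Generates the seeded multi-scenario phantom suite, segments every
#' phantom, and reports per-case and per-scenario IOU against the known
#' truth masks.
#'
#' @param n_per_scenario Phantoms per scenario.
#' @param base_seed Master seed for [make_suite()].
#' @param cfg A [pipeline_config()].
#' @param suite Optional pre-generated suite (from [make_suite()]) to reuse
#'   across configurations.
#' @return List with `cases` (a `data.frame`: scenario, case, iou,
#'   iterations, converged) and `medians` (named per-scenario median IOU).
#' @export
run_phantom_suite <- function(n_per_scenario = 20L, base_seed = 1L,
                              cfg = pipeline_config(), suite = NULL) {
  if (is.null(suite)) suite <- make_suite(n_per_scenario, base_seed)
  rows <- lapply(suite, function(case) {
    sr <- segment_nodule(case$image, cfg)
    data.frame(scenario = case$spec$scenario,
               iou = iou(sr$mask, case$mask),
               iterations = sr$iterations, converged = sr$converged,
               stringsAsFactors = FALSE)
  })
  cases <- do.call(rbind, rows)
  med <- tapply(cases$iou, cases$scenario, stats::median)
  list(cases = cases,
       medians = med[phantom_scenarios()[phantom_scenarios() %in%
                                           names(med)]])
}
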