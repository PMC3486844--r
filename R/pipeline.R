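#' Read a pipeline configuration file
#'
#' YAML configuration for [run_pipeline()]. Missing entries take the package
#' defaults, which mirror the canonical analysis settings: 5 ps frame spacing,
#' 1 ns burn-in, 50 ps map stride, k chosen by maximal overall silhouette over
#' 2..6, outlier threshold 0.8 A and Q(k) at k in (1, 10, 100, 200).
#'
#' @param path YAML file.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  as_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config a named list of settings (see the vignette for the schema).
#' @export
as_run_config <- function(config) {
  defaults <- list(dt = 5, stride_ps = 50, burn_in_ps = 1000,
                   k_range = c(2L, 6L), seed = 1L, n_init = 10L,
                   outlier_threshold = 0.8, q_ks = c(1L, 10L, 100L, 200L),
                   n_modes = 10L, dims = 2L)
  for (nm in names(defaults)) config[[nm]] <- config[[nm]] %||% defaults[[nm]]
  if (config$stride_ps <= 0) stop("stride must be positive")
  if (config$burn_in_ps < 0) stop("burn-in must be >= 0")
  if (is.null(config$input)) stop("config needs an 'input' section")
  if (is.null(config$output_dir)) stop("config needs an output_dir")
  structure(config, class = "run_config")
}

# Resolve the configured input into an ensemble (+ optional synthetic truth).
resolve_input <- function(config) {
  inp <- config$input
  kind <- inp$kind %||% "pdb_multimodel"
  if (kind == "synthetic") {
    syn <- inp$synthetic %||% inp
    gkind <- syn$generator %||% "two_state"
    K <- syn$K %||% 2000L
    noise <- syn$noise_sd %||% 0.08
    seed <- syn$seed %||% config$seed
    if (gkind == "two_state") {
      ra <- make_reference_pocket(cleft_base_distance = syn$cleft_a %||% 6.3)
      rb <- make_reference_pocket(cleft_base_distance = syn$cleft_b %||% 9.0)
      lab <- generate_two_state(ra, rb, switch_prob = syn$switch_prob %||% 0.02,
                                noise_sd = noise, K = K, dt = config$dt, seed = seed)
      list(ens = lab$ensemble, truth = lab, reference = rb)
    } else if (gkind == "harmonic") {
      ra <- make_reference_pocket(cleft_base_distance = syn$cleft_a %||% 6.3)
      lab <- generate_harmonic(ra, noise_sd = noise, K = K, dt = config$dt,
                               seed = seed)
      list(ens = lab$ensemble, truth = lab, reference = ra)
    } else stop("unknown synthetic generator: ", gkind)
  } else {
    ens <- load_ensemble(inp$path, format = kind, topology = inp$topology,
                         dt = config$dt)
    ref <- if (!is.null(config$reference))
      load_reference(config$reference$path, config$reference$model %||% 1L)
    list(ens = ens, truth = NULL, reference = ref)
  }
}

write_tsv_df <- function(df, path) {
  for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full ensemble-analysis pipeline
#'
#' Orchestrates every stage over one ensemble: fluctuation/flexibility
#' matrices and Theta, the strided dRMSD dissimilarity matrix, silhouette-
#' validated k-means with medoids and outliers, the 2D classical-MDS map, the
#' Q(k) profile and mean-absolute-difference matrix against a reference
#' structure, the cleft-distance distribution with Gaussian fits and open
#' fraction, dwell-time kinetics, and the RMSIP convergence check. All numeric
#' artifacts are written as TSV/JSON into the output directory together with a
#' manifest (config echo, package version, per-file MD5); reruns with an
#' identical config byte-match every numeric output.
#'
#' @param config a `run_config` (see [read_run_config()] / [as_run_config()]).
#' @return the output directory, invisibly; the manifest lists all artifacts.
#' @export
run_pipeline <- function(config) {
  config <- as_run_config(unclass(config))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  files <- character(0)
  emit <- function(obj, name, format) {
    p <- file.path(out, name)
    if (format == "tsv_df") write_tsv_df(obj, p) else write_results(obj, p, format)
    files <<- c(files, name)
    p
  }
  fail_manifest <- function(e) {
    man <- list(status = "failed", failed_stage = stage, error = conditionMessage(e),
                files = files, config = unclass(config),
                package_version = as.character(utils::packageVersion("ensdist")))
    jsonlite::write_json(man, file.path(out, "manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  }

  tryCatch({
    stage <- "input"
    inp <- resolve_input(config)
    ens <- inp$ens
    message("input: K = ", n_frames(ens), " frames, N = ", n_residues(ens), " residues")
    if (!is.null(inp$truth)) {
      emit(list(true_labels = inp$truth$true_labels,
                true_parameters = inp$truth$true_parameters),
           "synthetic_truth.json", "json")
    }

    stage <- "selection"
    sel <- NULL
    conf1 <- get_frame(ens, 1L)
    if (!is.null(config$selection)) {
      sel <- select_binding_site(conf1, config$selection$strand, config$selection$helix)
    } else if (!is.null(inp$truth)) {
      # synthetic pockets are built strand-first, helix-second
      ns <- sum(ens$labels$resid == "VAL")
      sel <- residue_selection(seq_len(n_residues(ens)),
                               blocks = list(strand = seq_len(ns),
                                             helix = (ns + 1L):n_residues(ens)))
    }

    stage <- "fluctuation"
    fmat <- fluctuation_matrix(ens, sel)
    xmat <- flexibility_matrix(ens, sel)
    emit(fmat, "fluctuation.tsv", "tsv")
    emit(xmat, "flexibility.tsv", "tsv")
    if (!is.null(sel) && !is.null(sel$blocks) && length(sel$blocks) >= 2L) {
      emit(cross_submatrix(fmat, sel), "fluctuation_strand_helix.tsv", "tsv")
      emit(cross_submatrix(xmat, sel), "flexibility_strand_helix.tsv", "tsv")
    }
    theta_all <- overall_fluctuation(ens, sel, "all_pairs")
    theta <- list(theta_all_pairs = theta_all$theta,
                  n_residues = theta_all$n_residues, n_frames = theta_all$n_frames)
    if (!is.null(sel) && !is.null(sel$blocks) && length(sel$blocks) >= 2L)
      theta$theta_cross_block <- overall_fluctuation(ens, sel, "cross_block")$theta
    emit(theta, "theta.json", "json")
    message("theta (all pairs) = ", signif(theta$theta_all_pairs, 4), " A")

    stage <- "dissimilarity"
    stride <- max(1L, as.integer(round(config$stride_ps / config$dt)))
    frames <- strided_frames(ens, stride, config$burn_in_ps)
    message("map subset: ", length(frames), " frames (stride ", stride,
            ", burn-in ", config$burn_in_ps, " ps)")
    dis <- dissimilarity_matrix(ens, sel, stride = stride, burn_in = config$burn_in_ps)
    emit(dis, "dissimilarity.tsv", "tsv")

    stage <- "clustering"
    ks <- seq(config$k_range[1L], config$k_range[length(config$k_range)])
    ks <- ks[ks <= length(frames)]
    sk <- select_k(ens, sel, k_range = ks, seed = config$seed,
                   n_init = config$n_init, frames = frames)
    best <- sk$results[[paste0("k", sk$best_k)]]
    message("best k = ", sk$best_k, " (S_OVER = ", signif(best$s_over, 4), ")")
    emit(list(best_k = sk$best_k, s_over = as.list(sk$s_over),
              wcss = lapply(sk$results, `[[`, "wcss"),
              sizes = lapply(sk$results, `[[`, "sizes"),
              seed = config$seed, n_init = config$n_init),
         "clusters.json", "json")
    emit(data.frame(frame = frames, label = best$labels,
                    silhouette = best$silhouette), "labels.tsv", "tsv_df")

    stage <- "embedding"
    emb <- cmds_embed(dis, dims = config$dims)
    emit(data.frame(id = emb$frame_ids, emb$coords), "embedding.tsv", "tsv_df")

    stage <- "medoids"
    med_all <- medoid(ens, sel, frames)
    outliers <- find_outliers(ens, sel, med_all, config$outlier_threshold, frames)
    emit(list(medoid_overall = med_all, medoids_per_cluster = best$medoids,
              outlier_threshold = config$outlier_threshold,
              outliers = outliers, n_outliers = length(outliers)),
         "medoids_outliers.json", "json")

    if (!is.null(inp$reference)) {
      stage <- "q_profile"
      qks <- config$q_ks[config$q_ks <= length(frames)]
      qp <- q_profile(ens, sel, inp$reference, ks = qks, frames = frames)
      emit(list(reference = qp$reference_id, ks = qp$ks,
                q_values = as.list(qp$q_values)), "qprofile.json", "json")
      message("Q profile: ", paste(names(qp$q_values),
                                   signif(qp$q_values, 3), sep = "=", collapse = ", "))

      stage <- "delta_matrix"
      n_nb <- min(100L, length(frames))
      nb <- qp$neighbor_frames[[length(qp$neighbor_frames)]][seq_len(n_nb)]
      refdm <- distance_matrix(inp$reference, sel)
      emit(mean_abs_difference_matrix(ens, refdm, sel, frames = nb),
           "delta.tsv", "tsv")
    }

    stage <- "cleft"
    pair <- config$cleft_pair
    if (is.null(pair) && !is.null(sel) && !is.null(sel$blocks)) {
      lb <- ens$labels
      pair <- list(list(chain = lb$chain[sel$blocks$strand[length(sel$blocks$strand)]],
                        resno = lb$resno[sel$blocks$strand[length(sel$blocks$strand)]]),
                   list(chain = lb$chain[sel$blocks$helix[1L]],
                        resno = lb$resno[sel$blocks$helix[1L]]))
    }
    if (!is.null(pair)) {
      series <- cleft_distance_series(ens, pair[[1L]], pair[[2L]])
      emit(data.frame(time_ps = series$frame_times %||% seq_along(series$values),
                      distance = series$values), "cleft_series.tsv", "tsv_df")
      fit <- fit_gaussians(series)
      open14 <- open_fraction(series, config$open_threshold %||% 14)
      emit(list(residue_pair = series$residue_pair,
                n_components = fit$n_components, means = fit$means,
                sds = fit$sds, weights = fit$weights, bic = as.list(fit$bic),
                open_threshold = config$open_threshold %||% 14,
                open_fraction = open14$fraction, open_count = open14$count),
           "cleft_fit.json", "json")
      message("cleft fit: ", fit$n_components, " component(s), means ",
              paste(signif(fit$means, 4), collapse = ", "), " A")
    }

    stage <- "kinetics"
    kin <- NULL
    if (sk$best_k >= 2L && !is.null(ens$dt)) {
      Dsub <- pair_dists(ens, sel, frames)
      cent <- t(vapply(best$cluster_means, function(m) m[lower.tri(m)],
                       numeric(ncol(Dsub))))
      sig <- sqrt(d2_to_centroids(Dsub, cent)[cbind(seq_along(frames), best$labels)])
      kin <- tryCatch(
        cluster_kinetics(best$labels, dt = config$dt * stride, signal = sig),
        error = function(e) NULL)
    }
    if (!is.null(kin)) {
      emit(list(mean_intercluster_transition_time_ps = kin$mean_intercluster_transition_time,
                mean_intracluster_relaxation_time_ps = kin$mean_intracluster_relaxation_time,
                n_transitions = kin$n_transitions,
                dwell_times_ps = unname(kin$dwell_times),
                dwell_clusters = names(kin$dwell_times)),
           "kinetics.json", "json")
    }

    stage <- "rmsip"
    conv <- rmsip(ens, sel, n_modes = min(config$n_modes, length(selection_indices(sel, n_residues(ens))) * 3L))
    emit(list(rmsip = conv$rmsip, n_modes = conv$n_modes, split = conv$split),
         "rmsip.json", "json")
    message("RMSIP (halves) = ", signif(conv$rmsip, 3))

    stage <- "manifest"
    man <- list(status = "complete",
                package_version = as.character(utils::packageVersion("ensdist")),
                config = unclass(config),
                files = as.list(stats::setNames(
                  unname(tools::md5sum(file.path(out, files))), files)))
    jsonlite::write_json(man, file.path(out, "manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }, error = fail_manifest)
  invisible(out)
}

#' Summarise a completed pipeline run
#'
#' Reads the manifest and artifacts of a [run_pipeline()] output directory and
#' prints a single human-readable summary (Theta, chosen k and S_OVER, medoids
#' and outlier count, Q values, cleft fit, kinetics, RMSIP). Artifacts missing
#' from the run are reported as "not computed".
#'
#' @param run_dir pipeline output directory.
#' @return invisibly, a named list of the summarised quantities.
#' @export
report <- function(run_dir) {
  man_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(man_path)) {
    have <- list.files(run_dir)
    stop("no manifest.json in ", run_dir, "; expected artifacts: ",
         "theta.json, clusters.json, medoids_outliers.json, ... (found: ",
         if (length(have)) paste(have, collapse = ", ") else "nothing", ")")
  }
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  grab <- function(name) {
    p <- file.path(run_dir, name)
    if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else NULL
  }
  theta <- grab("theta.json"); cl <- grab("clusters.json")
  mo <- grab("medoids_outliers.json"); qp <- grab("qprofile.json")
  cf <- grab("cleft_fit.json"); kin <- grab("kinetics.json"); cv <- grab("rmsip.json")
  nc <- function(x, fmt = "%s") if (is.null(x)) "not computed" else sprintf(fmt, x)

  cat("== ensdist run summary ==\n")
  cat("status:", man$status %||% "unknown", "\n")
  cat("Theta (all pairs):", nc(theta$theta_all_pairs, "%.4g A"), "\n")
  if (!is.null(theta$theta_cross_block))
    cat("Theta (strand x helix):", sprintf("%.4g A", theta$theta_cross_block), "\n")
  cat("best k:", nc(cl$best_k), " S_OVER:",
      if (is.null(cl)) "not computed" else
        sprintf("%.3f", cl$s_over[[paste0("k", cl$best_k)]]), "\n")
  cat("medoids per cluster:", if (is.null(mo)) "not computed" else
    paste(mo$medoids_per_cluster, collapse = ", "), "\n")
  cat("outliers (>=", if (is.null(mo)) "?" else mo$outlier_threshold, "A):",
      nc(mo$n_outliers), "\n")
  cat("Q values:", if (is.null(qp)) "not computed" else
    paste(names(qp$q_values), signif(unlist(qp$q_values), 3), sep = "=", collapse = ", "),
    "\n")
  cat("cleft fit:", if (is.null(cf)) "not computed" else
    sprintf("%d component(s); means %s A; open fraction %.4g", cf$n_components,
            paste(signif(cf$means, 4), collapse = "/"), cf$open_fraction), "\n")
  cat("kinetics:", if (is.null(kin)) "not computed" else
    sprintf("transition %.4g ps, relaxation %s", kin$mean_intercluster_transition_time_ps,
            if (is.null(kin$mean_intracluster_relaxation_time_ps) ||
                is.na(kin$mean_intracluster_relaxation_time_ps)) "n/a"
            else sprintf("%.4g ps", kin$mean_intracluster_relaxation_time_ps)), "\n")
  cat("RMSIP:", nc(cv$rmsip, "%.3f"), "\n")
  invisible(list(manifest = man, theta = theta, clusters = cl, medoids = mo,
                 qprofile = qp, cleft = cf, kinetics = kin, rmsip = cv))
}
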