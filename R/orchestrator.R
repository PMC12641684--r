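# End-to-end experiment driver: synthetic cohorts -> segmentation ->
# radiomics + latents -> NMF -> classifier grid -> comparison statistics,
# under one master seed, with a content-hash manifest of every
# intermediate for reproducibility checks.

#' Experiment configuration
#'
#' One master seed fans out deterministically to every stochastic stage.
#' `scale = "desk"` is the CPU-friendly default; `scale = "published"` sets
#' the published network geometry (128^3/64^3 inputs, 512-channel
#' bottlenecks, 64^3 autoencoder patches, 128 NMF components) and is
#' intended for shape validation via `dry_run`, not for training on a
#' laptop.
#'
#' @param scale "desk" or "published".
#' @param n_train,n_test cohort sizes.
#' @param seed master seed.
#' @param phantom,net,vaegan,radiomics,labels stage configurations
#'   (defaults depend on `scale`).
#' @param nmf_k NMF components per feature source.
#' @param trees ensemble size for the tree classifiers.
#' @param outcomes outcome labels to model.
#' @param folds_k cross-validation folds.
#' @param seg_epochs,n_seg_train segmentation training length and cases.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(scale = c("desk", "published"),
                              n_train = 200L, n_test = 100L, seed = 1L,
                              phantom = phantom_config(),
                              net = NULL, vaegan = NULL,
                              radiomics = radiomics_config(filters = "log"),
                              labels = label_model(),
                              nmf_k = 16L, trees = 300L,
                              outcomes = c("poor_outcome", "exp3", "exp6",
                                           "exp9"),
                              folds_k = 5L, seg_epochs = 12L,
                              n_seg_train = 14L) {
  scale <- match.arg(scale)
  if (is.null(net))
    net <- if (scale == "published")
      multiscale_net_config(full_res_shape = c(128L, 128L, 128L),
                            base_channels = 32L, depth = 4L,
                            bottleneck_channels = 512L,
                            deep_supervision_levels = 2L)
    else multiscale_net_config()
  if (is.null(vaegan))
    vaegan <- if (scale == "published")
      vaegan_config(patch_shape = c(64L, 64L, 64L), latent_channels = 512L,
                    depth = 4L)
    else vaegan_config(epochs = 10L)
  if (scale == "published" && nmf_k == 16L) nmf_k <- 128L
  structure(list(scale = scale, n_train = as.integer(n_train),
                 n_test = as.integer(n_test), seed = as.integer(seed),
                 phantom = phantom, net = net, vaegan = vaegan,
                 radiomics = radiomics, labels = labels,
                 nmf_k = as.integer(nmf_k), trees = as.integer(trees),
                 outcomes = outcomes, folds_k = as.integer(folds_k),
                 seg_epochs = as.integer(seg_epochs),
                 n_seg_train = as.integer(n_seg_train)),
            class = "experiment_config")
}

#' Validate an experiment configuration without computing
#'
#' Checks every cross-stage shape constraint (network divisibility,
#' bottleneck geometry, patch shapes, NMF rank versus source widths) and
#' returns the implied tensor shapes.
#'
#' @param cfg an `experiment_config`.
#' @return List of implied shapes (invisibly on success).
#' @export
validate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  bs <- bottleneck_shapes(cfg$net)
  vs <- c(cfg$vaegan$latent_channels,
          cfg$vaegan$patch_shape %/% 2L^cfg$vaegan$depth)
  widths <- c(seg = sum(vapply(bs, prod, numeric(1))), vaegan = prod(vs))
  if (cfg$nmf_k > cfg$n_train)
    stop("nmf_k exceeds the number of training cases")
  if (any(cfg$nmf_k > widths))
    stop("nmf_k exceeds a latent source width")
  if (cfg$folds_k < 2) stop("need at least 2 folds")
  invisible(list(bottlenecks = bs, vae_latent = vs, source_widths = widths))
}

# Content hash of any R object (serialized, uncompressed).
manifest_hash <- function(obj) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  saveRDS(obj, tmp, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full experiment
#'
#' Executes synth -> segmentation training -> radiomics and latent
#' extraction -> leakage-guarded NMF + classifier grid -> pipeline
#' comparison statistics. Each stage's output is content-hashed into the
#' manifest; rerunning with the same configuration reproduces the
#' manifest.
#'
#' @param cfg an `experiment_config`.
#' @param out_dir optional directory for CSV/markdown outputs.
#' @param dry_run if `TRUE`, only validate and return implied shapes.
#' @return List: `grid` (`result_grid`), `comparisons` (per outcome),
#'   `seg_dice` (held-out Dice of the segmentation model), `manifest`.
#' @export
run_experiment <- function(cfg, out_dir = NULL, dry_run = FALSE) {
  shapes <- validate_experiment(cfg)
  if (dry_run) return(list(shapes = shapes, manifest = NULL))
  seed <- cfg$seed
  manifest <- list(config = manifest_hash(cfg))
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    manifest[[name]] <<- manifest_hash(res)
    res
  }

  train <- stage("synth_train",
                 generate_cohort(cfg$phantom, cfg$n_train, cfg$labels,
                                 seed = seed + 101L))
  test <- stage("synth_test",
                generate_cohort(cfg$phantom, cfg$n_test, cfg$labels,
                                seed = seed + 202L))
  labels <- rbind(cohort_manifest(train), cohort_manifest(test))
  labels$case_id <- c(paste0("tr_", labels$case_id[seq_along(train)]),
                      paste0("te_", labels$case_id[cfg$n_train +
                                                     seq_along(test)]))
  all_cases <- c(train, test)
  for (i in seq_along(all_cases)) all_cases[[i]]$case_id <- labels$case_id[i]
  train_ids <- labels$case_id[seq_along(train)]
  test_ids <- setdiff(labels$case_id, train_ids)

  seg <- stage("segmentation", {
    m <- build_multiscale_unet(cfg$net, seed = seed + 11L)
    train_segmentation(m, train[seq_len(min(cfg$n_seg_train, length(train)))],
                       epochs = cfg$seg_epochs, seed = seed + 12L)
  })
  ho <- train[(length(train) - min(8L, length(train) %/% 4L) + 1L):
                length(train)]
  seg_dice <- vapply(ho, function(cs)
    dice_coefficient(predict_mask(seg, cs$image), cs$mask), numeric(1))

  vae <- stage("vaegan", {
    vcfg <- cfg$vaegan
    vcfg$seed <- seed + 21L
    patches <- lapply(train[seq_len(min(cfg$n_seg_train, length(train)))],
                      function(cs)
                        crop_roi(normalize_intensity(cs$image),
                                 dilate_mask(cs$mask, 5L), vcfg$patch_shape))
    train_vaegan(patches, vcfg)
  })

  rad <- stage("radiomics", radiomics_blocks(all_cases, cfg$radiomics))
  lat <- stage("latents", latent_blocks(seg, vae, all_cases))
  blocks <- c(list(radiomics_all = rad$all, shape = rad$shape), lat)

  grid <- stage("grid",
                run_grid(blocks, labels, train_ids, test_ids,
                         specs = classifier_specs(seed = seed + 31L,
                                                  trees = cfg$trees),
                         outcomes = cfg$outcomes, nmf_k = cfg$nmf_k,
                         folds_k = cfg$folds_k, seed = seed + 32L))
  comparisons <- stage("stats", {
    cm <- lapply(cfg$outcomes, function(oc)
      compare_pipelines(grid, oc, split = "test"))
    names(cm) <- cfg$outcomes
    cm
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(grid, file.path(out_dir, "result_grid.csv"),
                     row.names = FALSE)
    for (oc in cfg$outcomes)
      write_stats_report(comparisons[[oc]], out_dir, oc)
    writeLines(paste(names(manifest),
                     vapply(manifest, identity, character(1)), sep = "  "),
               file.path(out_dir, "manifest.txt"))
  }
  list(grid = grid, comparisons = comparisons, seg_dice = seg_dice,
       manifest = manifest)
}

#' Read / write experiment configurations as YAML
#'
#' @param cfg an `experiment_config`.
#' @param path YAML file path.
#' @return `write_experiment_yaml`: the path; `read_experiment_yaml`: an
#'   `experiment_config`.
#' @export
write_experiment_yaml <- function(cfg, path) {
  plain <- lapply(cfg, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_experiment_yaml
#' @export
read_experiment_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- experiment_config(
    scale = y$scale, n_train = y$n_train, n_test = y$n_test, seed = y$seed,
    phantom = do.call(phantom_config, y$phantom),
    net = do.call(multiscale_net_config,
                  y$net[setdiff(names(y$net), "half_res_shape")]),
    vaegan = do.call(vaegan_config, y$vaegan),
    radiomics = do.call(radiomics_config, y$radiomics),
    labels = do.call(label_model, y$labels),
    nmf_k = y$nmf_k, trees = y$trees, outcomes = y$outcomes,
    folds_k = y$folds_k, seg_epochs = y$seg_epochs,
    n_seg_train = y$n_seg_train)
  cfg
}
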