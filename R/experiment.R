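#' Build a named preprocessing chain for an experiment arm
#'
#' Known pre-treatments: `"raw"` (identity), `"snv"`, `"sg+snv"`
#' (Savitzky-Golay first derivative, window 11 / order 3, followed by SNV)
#' and `"epo"`. EPO needs fitting: its interference matrix is the per-cube
#' mean foreground spectrum of every training scene (one dominant
#' parasitic direction, c = 1 by default).
#'
#' @param name one of `"raw"`, `"snv"`, `"sg+snv"`, `"epo"`.
#' @param train_scenes list of `list(cube, truth)` training scenes
#'   (required for `"epo"`).
#' @param epo_components parasitic directions for `"epo"`.
#' @return A [pp_chain].
#' @export
build_chain <- function(name, train_scenes = NULL, epo_components = 1L) {
  switch(tolower(name),
         raw = pp_chain(),
         snv = pp_chain(pp_snv()),
         `sg+snv` = pp_chain(pp_sg(11L, 3L), pp_snv()),
         epo = {
           if (is.null(train_scenes))
             stop("the EPO chain needs `train_scenes` to fit the interference")
           M <- t(vapply(train_scenes, function(sc)
             colMeans(unfold(sc$cube, use_mask = TRUE)$values),
             numeric(length(train_scenes[[1L]]$cube$wavelengths))))
           pp_chain(pp_epo(epo_fit(M, epo_components)))
         },
         stop("unknown pre-treatment `", name,
              "`; valid options: raw, snv, sg+snv, epo"))
}

# unfold + preprocess + per-pixel labels for a list of scenes
gather_spectra <- function(scenes, chain) {
  Xs <- list(); ys <- list()
  for (sc in scenes) {
    fl <- unfold(sc$cube, use_mask = TRUE)
    Xs[[length(Xs) + 1L]] <- apply_chain(fl$values, chain)
    ys[[length(ys) + 1L]] <- sc$truth$labels[fl$coords]  # row-major scan order
  }
  list(X = do.call(rbind, Xs), y = unlist(ys))
}

experiment_defaults <- function(scenario, model) {
  p <- list(epochs = 100L, batch_size = 1024L, learning_rate = 0.01,
            max_lv = 10L, n_splits = 10L, svm_cost = 1,
            subsample = 1L, track_validation = TRUE,
            eval_splits = c("train", "val", "test"))
  if (scenario == "sweets") {
    p$d <- 10L; p$k2d <- 17L; p$k3d <- 7L; p$epo_components <- 1L
  } else {
    p$d <- 5L; p$k2d <- 7L; p$k3d <- 7L; p$subsample <- 4L
    p$epo_components <- 1L
  }
  p
}

#' Run one experiment arm (model x pre-treatment) on a synthetic dataset
#'
#' Fits the requested classifier on the training scenes and reports the
#' correct classification rate on every split, plus per-scene confusion
#' reports and classification maps for validation and test scenes.
#'
#' Models: `"plsda"` (latent-variable count picked by venetian-blinds CV),
#' `"svm"` (one-vs-one ECOC fusion of linear SVMs), `"pca-cnn"` (PC score
#' images + 2-D CNN) and `"3d-cnn"` (spectral-spatial patches + 3-D CNN).
#'
#' @param dataset a dataset from [generate_dataset()].
#' @param model one of `"plsda"`, `"svm"`, `"pca-cnn"`, `"3d-cnn"`.
#' @param chain a [pp_chain] or a pre-treatment name for [build_chain()].
#' @param seed seed for every stochastic step of this arm.
#' @param params named list overriding the scenario defaults (`d`, `k2d`,
#'   `k3d`, `epochs`, `batch_size`, `learning_rate`, `max_lv`,
#'   `n_splits`, `svm_cost`, `subsample`, `epo_components`,
#'   `track_validation` — score the validation scenes during CNN training —
#'   and `eval_splits` — which splits to predict and score).
#' @return List with `model`, `chain`, `ccr` (data frame: split, scene,
#'   ccr), `reports` (confusion reports), `maps` (label images), and the
#'   fitted objects.
#' @export
run_experiment <- function(dataset, model = c("plsda", "svm", "pca-cnn",
                                              "3d-cnn"),
                           chain = "raw", seed, params = list()) {
  model <- match.arg(model)
  if (missing(seed)) stop("`seed` is mandatory")
  scenario <- if (length(dataset$class_names) == 2L) "salmon" else "sweets"
  p <- utils::modifyList(experiment_defaults(scenario, model), params)
  if (!inherits(chain, "pp_chain"))
    chain <- build_chain(chain, train_scenes = dataset$train,
                         epo_components = p$epo_components)
  C <- length(dataset$class_names)
  tr <- gather_spectra(dataset$train, chain)
  set.seed(seed)

  fitted <- NULL
  predict_scene <- NULL
  if (model == "plsda") {
    sel <- select_lvs_venetian(tr$X, tr$y, max_lv = p$max_lv,
                               n_splits = p$n_splits)
    fitted <- plsda_fit(tr$X, tr$y, sel$n_lv)
    fitted_extra <- list(lv_curve = sel$curve, n_lv = sel$n_lv)
    predict_scene <- function(sc) {
      fl <- unfold(sc$cube, use_mask = TRUE)
      cl <- as.integer(predict(fitted, apply_chain(fl$values, chain)))
      refold(fl, matrix(cl, ncol = 1L), fill = 0, drop = TRUE)
    }
  } else if (model == "svm") {
    fitted <- ecoc_fit(tr$X, tr$y,
                       learner = svm_binary_learner(cost = p$svm_cost))
    fitted_extra <- list()
    predict_scene <- function(sc) {
      fl <- unfold(sc$cube, use_mask = TRUE)
      cl <- as.integer(predict(fitted, apply_chain(fl$values, chain)))
      refold(fl, matrix(cl, ncol = 1L), fill = 0, drop = TRUE)
    }
  } else if (model == "pca-cnn") {
    pca <- pca_fit(tr$X, p$d)
    train_ps <- do.call(rbind_patch_sets, lapply(dataset$train, function(sc)
      extract_patches(pca_project(sc$cube, pca, p$d, chain),
                      sc$cube$mask, labels = sc$truth, k = p$k2d)))
    val_ps <- if (p$track_validation && length(dataset$val))
      do.call(rbind_patch_sets, lapply(dataset$val, function(sc)
        extract_patches(pca_project(sc$cube, pca, p$d, chain),
                        sc$cube$mask, labels = sc$truth, k = p$k2d)))
    net <- cnn_build(cnn2d_spec(p$k2d, p$d, C))
    cfg <- train_config(learning_rate = p$learning_rate, epochs = p$epochs,
                        batch_size = p$batch_size, seed = seed,
                        validation = val_ps)
    fitted <- cnn_train(net, train_ps, cfg, class_names = dataset$class_names)
    fitted_extra <- list(pca = pca)
    predict_scene <- function(sc) {
      stack <- pca_project(sc$cube, pca, p$d, chain)
      predict_map(fitted, stack, sc$cube$mask)$map$labels
    }
  } else {  # 3d-cnn
    cubes_tr <- lapply(dataset$train, function(sc) preprocess_cube(sc$cube, chain))
    nb <- length(cubes_tr[[1L]]$wavelengths)
    train_ps <- do.call(rbind_patch_sets, lapply(seq_along(cubes_tr), function(i)
      extract_patches_3d(cubes_tr[[i]], p$k3d,
                         labels = dataset$train[[i]]$truth)))
    if (p$subsample > 1L) train_ps <- subsample_every(train_ps, p$subsample)
    val_ps <- if (p$track_validation && length(dataset$val))
      do.call(rbind_patch_sets, lapply(dataset$val, function(sc)
        extract_patches_3d(preprocess_cube(sc$cube, chain), p$k3d,
                           labels = sc$truth)))
    net <- cnn_build(cnn3d_spec(p$k3d, nb, C))
    cfg <- train_config(learning_rate = p$learning_rate, epochs = p$epochs,
                        batch_size = p$batch_size, seed = seed,
                        validation = val_ps)
    fitted <- cnn_train(net, train_ps, cfg, class_names = dataset$class_names)
    fitted_extra <- list()
    predict_scene <- function(sc) {
      predict_map(fitted, preprocess_cube(sc$cube, chain))$map$labels
    }
  }

  ccr_rows <- list(); reports <- list(); maps <- list()
  for (split in intersect(c("train", "val", "test"), p$eval_splits)) {
    for (i in seq_along(dataset[[split]])) {
      sc <- dataset[[split]][[i]]
      pred <- predict_scene(sc)
      rep_ <- confusion(sc$truth, pred)
      key <- paste0(split, i)
      reports[[key]] <- rep_
      maps[[key]] <- label_image(pred, dataset$class_names)
      ccr_rows[[length(ccr_rows) + 1L]] <-
        data.frame(split = split, scene = i, ccr = rep_$ccr)
    }
  }
  list(model = model, chain = chain, params = p, seed = seed,
       ccr = do.call(rbind, ccr_rows), reports = reports, maps = maps,
       fitted = fitted, extra = fitted_extra)
}

#' Concatenate patch sets (same geometry)
#' @param ... `patch_set`s with identical k and d.
#' @return A single `patch_set`; `source_shape` is taken from the first.
#' @export
rbind_patch_sets <- function(...) {
  pss <- list(...)
  stopifnot(length(pss) >= 1L)
  k <- pss[[1L]]$k; d <- pss[[1L]]$d
  for (ps in pss) stopifnot(ps$k == k, ps$d == d)
  structure(list(patches = do.call(rbind, lapply(pss, `[[`, "patches")),
                 centers = do.call(rbind, lapply(pss, `[[`, "centers")),
                 labels = unlist(lapply(pss, `[[`, "labels")),
                 k = k, d = d, source_shape = pss[[1L]]$source_shape),
            class = "patch_set")
}

#' Run a {model x pre-treatment} grid and tabulate CCRs
#'
#' Produces one row per arm with the correct classification rate (%) per
#' split, in the shape of the usual model-comparison tables.
#'
#' @param dataset a dataset from [generate_dataset()].
#' @param models character vector of models (see [run_experiment()]).
#' @param chains character vector of pre-treatment names.
#' @param seed master seed.
#' @param params overrides forwarded to every arm.
#' @return Data frame: model, pre_treatment, then `train`, `val`,
#'   `test1`, `test2`, ... columns with CCR in percent.
#' @export
run_grid <- function(dataset, models = c("plsda", "svm", "pca-cnn", "3d-cnn"),
                     chains = c("raw", "snv", "sg+snv"), seed,
                     params = list()) {
  if (missing(seed)) stop("`seed` is mandatory")
  rows <- list()
  for (m in models) for (ch in chains) {
    res <- run_experiment(dataset, m, ch, seed = seed, params = params)
    cc <- res$ccr
    splits <- unique(cc$split)
    vals <- list(model = m, pre_treatment = ch)
    for (sp in splits) {
      sub <- cc[cc$split == sp, ]
      if (sp == "test" && nrow(sub) > 1L) {
        for (i in seq_len(nrow(sub)))
          vals[[paste0("test", i)]] <- round(100 * sub$ccr[i], 2L)
      } else {
        vals[[sp]] <- round(100 * mean(sub$ccr), 2L)
      }
    }
    rows[[length(rows) + 1L]] <- as.data.frame(vals)
  }
  do.call(rbind, rows)
}

#' Save / load a fitted model with a JSON sidecar
#'
#' The object goes to an RDS file; a human-readable JSON sidecar records
#' its class and key metadata (class names, hyperparameters, seed) so runs
#' stay auditable without deserializing.
#'
#' @param object fitted model (pca/plsda/ecoc/cnn/epo or experiment result).
#' @param path `.rds` output path.
#' @return `path`, invisibly / the restored object.
#' @export
save_model <- function(object, path) {
  saveRDS(object, path)
  meta <- list(class = class(object)[1L])
  if (!is.null(object$class_names)) meta$class_names <- object$class_names
  if (!is.null(object$n_lv)) meta$n_lv <- object$n_lv
  if (!is.null(object$config)) meta$config <- object$config
  if (!is.null(object$spec)) meta$spec <- unclass(object$spec)
  jsonlite::write_json(meta, sub("\\.rds$", ".json", path, ignore.case = TRUE),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
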