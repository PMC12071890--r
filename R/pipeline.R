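#' Pipeline configuration
#'
#' One root seed drives every stochastic stage (case generation, network
#' initialization); per-stage seeds are derived from it by fixed offsets, so
#' a config + seed reproduces every numeric output bit-identically.
#'
#' @param out_dir output directory (created if missing); `NULL` keeps
#'   everything in memory.
#' @param seed root seed.
#' @param n_cases number of synthetic cases.
#' @param grid_shape,spacing_mm case grid (defaults sized for desk-scale
#'   runs; the physical extent matches a thorax field of view).
#' @param favor per-case dose-pair preference, recycled ("proton"/"photon").
#' @param prescription_gy per-case prescription, recycled.
#' @param n_train cases used to train the network.
#' @param net a [network_spec()].
#' @param train a [train_spec()].
#' @param stages named logical list enabling pipeline stages.
#' @param skip_align skip rigid alignment (phantom pairs are generated on a
#'   common frame).
#' @param halt_on_qa halt the run when preprocessing raises a QA flag.
#' @param threshold_pct NTCP relevance threshold (%).
#' @param lkb_path optional LKB parameter file (see [default_lkb_params()]).
#' @param noise_sd,hu_shift,deformation phantom generation controls.
#' @param failure failure-mode injection on case 1: `truncation` (FOV
#'   fraction) and `contrast` (logical) — QA fixtures.
#' @param write_nifti write volumes/doses as NIfTI under `out_dir`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = NULL, seed = 1L, n_cases = 4,
                            grid_shape = c(32, 32, 16),
                            spacing_mm = c(8, 8, 10),
                            favor = c("proton", "photon"),
                            prescription_gy = 60,
                            n_train = 1,
                            net = network_spec(levels = 2, base_channels = 8,
                                               convs_per_block = 1),
                            train = train_spec(learning_rate = 2e-3,
                                               batch_size = 2, epochs = 60),
                            stages = list(preprocess = TRUE, train = TRUE,
                                          predict = TRUE, evaluate = TRUE,
                                          dvh = TRUE, ntcp = TRUE,
                                          compare = TRUE),
                            skip_align = TRUE, halt_on_qa = TRUE,
                            threshold_pct = 0.05, lkb_path = NULL,
                            noise_sd = 3, hu_shift = 25,
                            deformation = list(n_blobs = 2,
                                               amplitude_mm = c(2, 5),
                                               width_mm = c(25, 45)),
                            failure = list(truncation = 0, contrast = FALSE),
                            write_nifti = FALSE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_cases = as.integer(n_cases),
                 grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 favor = favor, prescription_gy = prescription_gy,
                 n_train = as.integer(n_train), net = net, train = train,
                 stages = stages, skip_align = isTRUE(skip_align),
                 halt_on_qa = isTRUE(halt_on_qa),
                 threshold_pct = threshold_pct, lkb_path = lkb_path,
                 noise_sd = noise_sd, hu_shift = hu_shift,
                 deformation = deformation, failure = failure,
                 write_nifti = isTRUE(write_nifti)),
            class = "pipeline_config")
}

#' Generate one complete synthetic case
#'
#' A paired diagnostic/planning fixture: a clean thorax volume; the
#' planning CT is the anatomy deformed by a known smooth field plus a flat
#' treatment couch; the diagnostic CT is the undeformed anatomy with a
#' protocol HU shift inside the body, a curved diagnostic bed, and optional
#' contrast or lateral truncation failure modes.
#'
#' @param seed case seed.
#' @param grid_shape,spacing_mm case grid.
#' @param favor dose-pair preference ("proton" or "photon").
#' @param prescription_gy prescription dose (Gy).
#' @param noise_sd,hu_shift phantom HU noise and protocol shift.
#' @param deformation list(n_blobs, amplitude_mm, width_mm).
#' @param contrast,truncation failure-mode toggles for the dCT.
#' @return list with `dct`, `pct` ([image_volume()]s), `masks_dct`,
#'   `masks_pct` (ground truth), `dvf_true` ([dvf_field()]), `dose_specs`,
#'   `favor` and `seed`.
#' @export
make_case <- function(seed, grid_shape = c(32, 32, 16),
                      spacing_mm = c(8, 8, 10), favor = "proton",
                      prescription_gy = 60, noise_sd = 3, hu_shift = 25,
                      deformation = list(n_blobs = 2, amplitude_mm = c(2, 5),
                                         width_mm = c(25, 45)),
                      contrast = FALSE, truncation = 0) {
  spec0 <- phantom_spec(grid_shape = grid_shape, spacing_mm = spacing_mm,
                        couch_kind = "none", noise_sd = noise_sd,
                        random_seed = seed)
  ph <- make_thorax_phantom(spec0)
  dspec <- deformation_spec(n_blobs = deformation$n_blobs,
                            amplitude_mm = deformation$amplitude_mm,
                            width_mm = deformation$width_mm,
                            random_seed = seed + 1000L)
  dvf_true <- make_smooth_dvf(dspec, ph$volume)
  # planning CT: deformed anatomy on a flat couch
  pct_anat <- warp_volume(ph$volume, dvf_true)
  masks_pct <- lapply(ph$masks, warp_mask, dvf = dvf_true, spacing = spacing_mm)
  pcb <- add_couch(pct_anat, masks_pct$body, kind = "flat")
  masks_pct$couch <- pcb$couch_mask
  # diagnostic CT: original anatomy, protocol HU shift, curved bed
  dct_data <- ph$volume$data
  dct_data[ph$masks$body] <- dct_data[ph$masks$body] + hu_shift
  dct <- image_volume(dct_data, spacing_mm)
  if (contrast) {
    vessel <- ph$masks$heart & cpp_edt(!ph$masks$heart, spacing_mm) > 12
    dct <- add_contrast(dct, vessel, delta = 200)
  }
  dcb <- add_couch(dct, ph$masks$body, kind = "curved")
  masks_dct <- ph$masks
  masks_dct$body <- dcb$body_mask
  masks_dct$couch <- dcb$couch_mask
  dct <- dcb$volume
  if (truncation > 0) dct <- truncate_fov(dct, truncation)
  list(dct = dct, pct = pcb$volume, masks_dct = masks_dct,
       masks_pct = masks_pct, dvf_true = dvf_true,
       dose_specs = dose_spec_pair(favor, prescription_gy),
       favor = favor, seed = seed)
}

#' Write a quick-start demo case to disk
#'
#' Generates one synthetic case, writes dCT/pCT/masks/dose grids as NIfTI
#' plus a ready-to-run pipeline config (JSON), and returns the paths.
#'
#' @param out_dir target directory.
#' @param seed case seed.
#' @param favor dose-pair preference.
#' @param ... passed to [make_case()].
#' @return (invisibly) list of written paths.
#' @export
demo_case <- function(out_dir, seed = 1L, favor = "proton", ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cs <- make_case(seed, favor = favor, ...)
  sp <- cs$pct$spacing
  paths <- list(
    dct = file.path(out_dir, "dct.nii.gz"),
    pct = file.path(out_dir, "pct.nii.gz"),
    config = file.path(out_dir, "config.json"))
  write_volume(cs$dct, paths$dct)
  write_volume(cs$pct, paths$pct)
  mask_dir <- file.path(out_dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  for (nm in names(cs$masks_pct)) {
    p <- file.path(mask_dir, paste0(nm, ".nii.gz"))
    write_volume(image_volume(array(as.double(cs$masks_pct[[nm]]),
                                    dim = dim(cs$pct$data)), sp), p)
    paths[[paste0("mask_", nm)]] <- p
  }
  for (mod in c("photon", "proton")) {
    dose <- make_dose(cs$masks_pct, cs$dose_specs[[mod]], sp)
    p <- file.path(out_dir, paste0("dose_", mod, "_pct.nii.gz"))
    write_volume(dose, p)
    paths[[paste0("dose_", mod)]] <- p
  }
  cfg <- list(seed = seed, favor = favor,
              grid_shape = dim(cs$pct$data), spacing_mm = sp,
              files = lapply(paths, identity))
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Run the end-to-end modality-selection pipeline
#'
#' Stages, in dependency order: synthetic case generation; preprocessing
#' (couch removal, histogram-matching HU normalization, optional rigid
#' alignment); network training; synthetic-CT prediction (with contour
#' propagation via the predicted field); image evaluation (MAE/UQI); dose
#' and DVH panels for photon/proton on both CTs; LKB NTCP per endpoint; and
#' the modality comparison. Any stage failure halts with a stage-named
#' error after writing a partial manifest.
#'
#' @param config a [pipeline_config()].
#' @return list with `report` (modality report + DVH agreement + image
#'   metrics), `manifest`, and `cases` (per-case artifacts).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("need a pipeline_config")
  manifest <- list(config = config_manifest(config),
                   package_version = as.character(utils::packageVersion("sctselect")),
                   stages = list())
  finish_stage <- function(name, status = "complete") {
    manifest$stages[[name]] <<- status
    if (!is.null(config$out_dir))
      jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           force = TRUE)
  }
  fail_stage <- function(name, msg) {
    finish_stage(name, paste("failed:", msg))
    stop(sprintf("stage '%s' failed: %s", name, msg), call. = FALSE)
  }
  if (!is.null(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- phantom ------------------------------------------------------------
  favors <- rep(config$favor, length.out = config$n_cases)
  rx <- rep(config$prescription_gy, length.out = config$n_cases)
  cases <- lapply(seq_len(config$n_cases), function(i)
    make_case(config$seed + i, config$grid_shape, config$spacing_mm,
              favor = favors[i], prescription_gy = rx[i],
              noise_sd = config$noise_sd, hu_shift = config$hu_shift,
              deformation = config$deformation,
              contrast = i == 1 && isTRUE(config$failure$contrast),
              truncation = if (i == 1) config$failure$truncation else 0))
  finish_stage("phantom")

  # --- preprocess ----------------------------------------------------------
  if (isTRUE(config$stages$preprocess)) {
    for (i in seq_along(cases)) {
      dclean <- withCallingHandlers(
        remove_couch(cases[[i]]$dct),
        warning = function(w) invokeRestart("muffleWarning"))
      pclean <- remove_couch(cases[[i]]$pct)
      if (config$halt_on_qa && (dclean$qa$truncation || pclean$qa$truncation))
        fail_stage("preprocess",
                   sprintf("truncation QA flag raised on case %d", i))
      lut <- build_hu_lut(dclean$volume, pclean$volume,
                          dclean$body_mask, pclean$body_mask)
      dnorm <- apply_lut(dclean$volume, lut)
      if (!config$skip_align) {
        al <- rigid_align(dnorm, pclean$volume, dclean$body_mask,
                          pclean$body_mask)
        dnorm <- al$volume
        cases[[i]]$translation_mm <- al$translation_mm
      }
      cases[[i]]$dct_clean <- dnorm
      cases[[i]]$pct_clean <- pclean$volume
      cases[[i]]$body_dct <- dclean$body_mask
      cases[[i]]$body_pct <- pclean$body_mask
    }
    finish_stage("preprocess")
  }

  # --- train ---------------------------------------------------------------
  model <- build_network(config$net, seed = config$seed + 7000L)
  if (isTRUE(config$stages$train)) {
    idx <- seq_len(min(config$n_train, length(cases)))
    pairs <- lapply(cases[idx], function(cs)
      list(dct = cs$dct_clean, pct = cs$pct_clean))
    model <- train_dvfnet(pairs, model, config$train)
    finish_stage("train")
  }

  # --- predict -------------------------------------------------------------
  if (isTRUE(config$stages$predict)) {
    for (i in seq_along(cases)) {
      pr <- predict_sct(cases[[i]]$dct_clean, model,
                        hu_window = config$train$hu_window)
      cases[[i]]$sct <- pr$sct
      cases[[i]]$dvf <- pr$dvf
      cases[[i]]$masks_sct <- lapply(cases[[i]]$masks_dct, warp_mask,
                                     dvf = pr$dvf, spacing = config$spacing_mm)
    }
    finish_stage("predict")
  }

  # --- evaluate ------------------------------------------------------------
  image_metrics <- NULL
  if (isTRUE(config$stages$evaluate)) {
    image_metrics <- do.call(rbind, lapply(seq_along(cases), function(i) {
      cs <- cases[[i]]
      data.frame(case = i,
                 mae_sct_pct = mae(cs$sct, cs$pct_clean),
                 mae_dct_pct = mae(cs$dct_clean, cs$pct_clean),
                 uqi_sct_pct = uqi(cs$sct, cs$pct_clean),
                 ssim_sct_pct = ssim_volume(cs$sct, cs$pct_clean))
    }))
    finish_stage("evaluate")
  }

  # --- dvh -----------------------------------------------------------------
  dvh_deltas <- NULL
  if (isTRUE(config$stages$dvh)) {
    dvh_deltas <- do.call(rbind, lapply(seq_along(cases), function(i) {
      cs <- cases[[i]]
      sp <- config$spacing_mm
      panels <- list(
        sct = lapply(cs$dose_specs, function(ds)
          oar_panel(make_dose(cs$masks_sct, ds, sp), cs$masks_sct)),
        pct = lapply(cs$dose_specs, function(ds)
          oar_panel(make_dose(cs$masks_pct, ds, sp), cs$masks_pct)))
      cbind(case = i, delta_dvh_panel(panels$sct, panels$pct))
    }))
    finish_stage("dvh")
  }

  # --- ntcp ----------------------------------------------------------------
  ntcp_values <- NULL
  if (isTRUE(config$stages$ntcp)) {
    params <- default_lkb_params(config$lkb_path)
    rows <- list()
    for (i in seq_along(cases)) {
      cs <- cases[[i]]
      sp <- config$spacing_mm
      for (ct in c("sct", "pct")) {
        masks <- if (ct == "sct") cs$masks_sct else cs$masks_pct
        for (mod in c("photon", "proton")) {
          dose <- make_dose(masks, cs$dose_specs[[mod]], sp)
          for (p in params) {
            curve <- compute_dvh(dose, masks[[p$structure]],
                                 structure = p$structure)
            res <- lkb_ntcp(curve, p)
            rows[[length(rows) + 1]] <- data.frame(
              case = i, endpoint = p$endpoint, modality = mod, ct = ct,
              ntcp = res$ntcp, deff_gy = res$deff_gy)
          }
        }
      }
    }
    ntcp_values <- do.call(rbind, rows)
    finish_stage("ntcp")
  }

  # --- compare -------------------------------------------------------------
  report <- NULL
  if (isTRUE(config$stages$compare)) {
    verdict <- modality_verdict(ntcp_values, config$threshold_pct)
    dvh_sum <- agreement_summary(dvh_deltas)
    report <- list(modality = unclass_report(verdict),
                   dvh_agreement = dvh_sum,
                   image_metrics = image_metrics,
                   seed = config$seed)
    if (!is.null(config$out_dir)) {
      jsonlite::write_json(report, file.path(config$out_dir, "modality_report.json"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           force = TRUE, dataframe = "columns")
      write.csv(ntcp_values, file.path(config$out_dir, "ntcp_values.csv"),
                row.names = FALSE)
      write.csv(dvh_deltas, file.path(config$out_dir, "dvh_deltas.csv"),
                row.names = FALSE)
    }
    finish_stage("compare")
  }
  list(report = report, manifest = manifest, cases = cases, model = model,
       ntcp_values = ntcp_values, dvh_deltas = dvh_deltas)
}

unclass_report <- function(x) {
  out <- unclass(x)
  out$pairs <- as.list(out$pairs)
  out
}

config_manifest <- function(config) {
  cfg <- unclass(config)
  cfg$net <- unclass(cfg$net)
  cfg$train <- unclass(cfg$train)
  cfg
}
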