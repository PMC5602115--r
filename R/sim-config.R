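# YAML-driven simulation runs: one config file describes every generator
# input (seed mandatory), so a whole synthetic data set is reproducible
# from a single plain-text document.

#' Read and validate a simulation config
#'
#' The YAML schema has a mandatory top-level `seed` and optional sections:
#'
#' * `object_table`: arguments of [object_table_spec()] (minus `seed`);
#' * `image_stack`: arguments of [gen_scene_truth()] plus `psf_sigma_xy`,
#'   `psf_sigma_z`, `background`, `poisson`;
#' * `spectroscopy`: `c_true`, `dol_true`, `noise_sd`, `eps_dye`, `cf260`,
#'   `epsilons`, `n_initial_pmol`, `volume_l`.
#'
#' @param path Path to a YAML file.
#' @return The validated config list.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("simulation config must set `seed`")
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed)) {
    stop("`seed` must be an integer")
  }
  cfg
}

#' Generate synthetic data from a YAML config
#'
#' Runs every generator section found in the config (see
#' [read_sim_config()]) and writes its outputs under `outdir`: object
#' tables as `objects.tsv` (with truth columns in
#' `objects_truth.tsv`), stacks as `ref.tif` / `tgt.tif`, and
#' spectroscopy reads as `spectro.tsv`.
#'
#' @param config A config list from [read_sim_config()], or a path to a
#'   YAML file.
#' @param outdir Output directory (created if missing).
#' @return Named list of generated objects, invisibly.
#' @export
simulate_from_config <- function(config, outdir) {
  if (is.character(config)) config <- read_sim_config(config)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  out <- list(seed = config$seed)
  if (!is.null(config$object_table)) {
    spec <- do.call(object_table_spec,
                    c(config$object_table, list(seed = config$seed)))
    tab <- gen_object_table(spec)
    write_object_table(tab, file.path(outdir, "objects.tsv"))
    write_object_table(tab, file.path(outdir, "objects_truth.tsv"),
                       truth = TRUE)
    out$object_table <- tab
  }
  if (!is.null(config$image_stack)) {
    p <- config$image_stack
    scene_args <- p[intersect(names(p),
                              names(formals(gen_scene_truth)))]
    scene_args$seed <- config$seed
    if (!is.null(scene_args$dim)) scene_args$dim <- unlist(scene_args$dim)
    truth <- do.call(gen_scene_truth, scene_args)
    stack_args <- p[intersect(names(p), c("psf_sigma_xy", "psf_sigma_z",
                                          "background", "poisson"))]
    st <- do.call(gen_image_stack, c(list(truth = truth), stack_args))
    write_stack_tiff(st$ref, file.path(outdir, "ref.tif"))
    write_stack_tiff(st$tgt, file.path(outdir, "tgt.tif"))
    out$image_stack <- st
  }
  if (!is.null(config$spectroscopy)) {
    p <- config$spectroscopy
    dye <- dye_spec(p$eps_dye, p$cf260)
    pool <- oligo_pool_spec(unlist(p$epsilons),
                            n_initial_pmol = p$n_initial_pmol %||% 1000,
                            volume_l = p$volume_l %||% 50e-6)
    rd <- gen_spectro_read(p$c_true, p$dol_true, pool, dye,
                           noise_sd = p$noise_sd %||% 0,
                           seed = config$seed)
    write.table(data.frame(od260 = rd$od260, od_dye = rd$od_dye),
                file.path(outdir, "spectro.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out$spectroscopy <- rd
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
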