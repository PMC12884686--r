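#' Write / read a model configuration as YAML
#'
#' Serializes the parameter blocks that define a simulation - cell
#' parameters, connectivity specification, drive and synapse kinetics - as
#' one YAML document, and restores them to constructor-validated objects.
#' Gating kinetics travel with the PV block; the calibrated `h_form` switch
#' is preserved.
#'
#' @param path file path
#' @param pv a [pv_cell_params()]
#' @param ecell an [e_cell_params()]
#' @param spec a [connectivity_spec()]
#' @param drive a [drive_spec()]
#' @param syn a [synapse_params()]
#' @return `write_model_config` returns `path` invisibly;
#'   `read_model_config` returns a named list of the restored objects
#'   (`pv`, `ecell`, `spec`, `drive`, `syn`).
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' write_model_config(path, spec = connectivity_spec(seed = 3))
#' read_model_config(path)$spec$seed
#' @export
write_model_config <- function(path, pv = pv_cell_params(),
                               ecell = e_cell_params(),
                               spec = connectivity_spec(),
                               drive = drive_spec(),
                               syn = synapse_params()) {
  strip <- function(x) lapply(unclass(x), function(v)
    if (inherits(v, "gating_kinetics")) unclass(v) else v)
  cfg <- list(
    pv = strip(pv)[setdiff(names(unclass(pv)), "kinetics")],
    pv_kinetics = lapply(pv$kinetics, unclass),
    ecell = strip(ecell),
    connectivity = strip(spec),
    drive = strip(drive),
    synapses = lapply(unclass(syn), unclass))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  kin <- lapply(cfg$pv_kinetics, function(k) do.call(gating_kinetics, k))
  pv_args <- cfg$pv
  pv_args$kinetics <- kin
  syn <- cfg$synapses
  list(
    pv = do.call(pv_cell_params, pv_args),
    ecell = do.call(e_cell_params, cfg$ecell),
    spec = do.call(connectivity_spec, cfg$connectivity),
    drive = do.call(drive_spec, cfg$drive),
    syn = synapse_params(gaba_rev_ii = syn$II$e_rev,
                         gaba_rev_ie = syn$IE$e_rev,
                         ampa_rev = syn$EI$e_rev))
}
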