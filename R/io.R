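# Serialization of network specifications and canonical fixture
# generation.  JSON is the canonical on-disk format; YAML is accepted on
# input when the yaml package is available.

#' Write a network specification to JSON
#'
#' @param net a [glif_network()].
#' @param path output file path.
#' @param meta optional named list stored alongside the network specification.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, meta = NULL) {
  stopifnot(inherits(net, "glif_network"))
  obj <- list(format = "glifnet-network", version = 1L,
              neurons = net$neurons, synapses = net$synapses)
  if (!is.null(meta)) obj$meta <- meta
  jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, null = "null", na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read and validate a network specification
#'
#' Accepts the JSON written by [write_network()]; files ending in
#' `.yml`/`.yaml` are parsed with the yaml package if installed.  The
#' result passes through [glif_network()], so every invariant is checked
#' and violations produce errors naming the offending field.
#'
#' @param path input file path.
#' @return A [glif_network()].
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML specs requires the yaml package")
    obj <- yaml::read_yaml(path)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(obj$neurons))
    stop("not a network spec: missing `neurons`")
  syn <- obj$synapses
  if (!is.null(syn) && !is.data.frame(syn)) syn <- as.data.frame(syn)
  glif_network(as.data.frame(obj$neurons), syn)
}

#' Generate the canonical fixture set
#'
#' Writes, under `outdir`: the two worked-example transmission pathways
#' (flat-transient `m = 0` and rising-transient `m = -5`), population
#' versions at several sizes, step-stimulus files at 5, 10 and 20 nA,
#' and the default reflex plant configuration.  File contents are
#' deterministic for a fixed seed.
#'
#' @param outdir output directory (created if needed).
#' @param seed integer seed for the population conductance splits.
#' @param N_values population sizes to emit.
#' @return Character vector of written paths, invisibly.
#' @export
generate_fixtures <- function(outdir, seed = 1,
                              N_values = c(1, 5, 10, 20)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  d1 <- design_pathway(k_syn = 1, Es = 160, m = 0)
  d2 <- design_pathway(k_syn = 1, Es = 160, m = -5, tau_mem_bar = 500)
  emit <- function(net, name, meta) {
    p <- file.path(outdir, name)
    write_network(net, p, meta = meta)
    paths <<- c(paths, p)
  }
  emit(build_population_pathway(d1, N = 1), "example1_m0.json",
       list(design = "transmission k_syn = 1, m = 0"))
  emit(build_population_pathway(d2, N = 1), "example2_m-5.json",
       list(design = "transmission k_syn = 1, m = -5"))
  for (N in N_values)
    emit(build_population_pathway(d1, N = N, seed = seed + N),
         sprintf("population_m0_N%d.json", N),
         list(design = sprintf("population pathway, N = %d", N),
              seed = seed + N))
  for (I in c(5, 10, 20)) {
    p <- file.path(outdir, sprintf("stim_%dnA.json", I))
    jsonlite::write_json(stim_step(1, I, t_start = 0, t_end = 1e9),
                         p, dataframe = "columns", digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p)
  }
  p <- file.path(outdir, "reflex_plant.json")
  jsonlite::write_json(unclass(plant_params()), p, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
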