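#' Read / write model parameter files
#'
#' Channel models are stored as flat key-value YAML: a `type` field
#' (`"tetracube"` or `"msa"`) and one key per parameter (e.g.
#' `fast_open_A`, `fast_open_Vhalf`, ...). [load_model()] builds the
#' corresponding `channel_model` directly.
#'
#' @param path File path.
#' @return `read_model_config()`: list with `type` and `params`;
#'   `load_model()`: a `channel_model`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$type))
  list(type = cfg$type, params = cfg[setdiff(names(cfg), "type")])
}

#' @rdname read_model_config
#' @param type Model type.
#' @param params Named parameter list.
#' @export
write_model_config <- function(params, type, path) {
  yaml::write_yaml(c(list(type = type), lapply(params, as.numeric)), path,
                   precision = 15)
  invisible(path)
}

#' @rdname read_model_config
#' @export
load_model <- function(path) {
  cfg <- read_model_config(path)
  switch(cfg$type,
         tetracube = tetracube_model(params = cfg$params),
         msa = msa_model(cfg$params),
         stop("unknown model type: ", cfg$type, call. = FALSE))
}

#' Read / write drug specification files
#'
#' Flat key-value YAML with keys `name`, `ka`, `kd`, `CA`, `CF`, `CS`,
#' `concentration_uM`.
#'
#' @param path File path.
#' @param drug A [drug_spec()].
#' @return A [drug_spec()] (read) or the path, invisibly (write).
#' @export
read_drug_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  drug_spec(ka = cfg$ka, kd = cfg$kd, CA = cfg$CA %||% 1,
            CF = cfg$CF %||% 1, CS = cfg$CS %||% 1,
            concentration = cfg$concentration_uM %||% 0,
            name = cfg$name)
}

#' @rdname read_drug_config
#' @export
write_drug_config <- function(drug, path) {
  yaml::write_yaml(list(name = drug$name, ka = drug$ka, kd = drug$kd,
                        CA = drug$CA, CF = drug$CF, CS = drug$CS,
                        concentration_uM = drug$concentration),
                   path, precision = 15)
  invisible(path)
}

#' Write the shipped drug fixtures to a directory
#'
#' Emits YAML files for the four prototypical mechanisms (`FI_fb`,
#' `FI_sb`, `SI_fb`, `SI_sb` at 30 uM) and a CSV table of the 100-drug
#' parameter grid (ten kinetics pairs with fixed resting affinity
#' `ka/kd = 5e-3`, times stabilizing factors 2/5/10/20/50 on either the
#' fast or the slow gate).
#'
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written.
#' @export
fixture_drugs <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (d in prototype_drugs()) {
    p <- file.path(dir, paste0(d$name, ".yaml"))
    write_drug_config(d, p)
    paths <- c(paths, p)
  }
  grid <- drug_grid()
  p <- file.path(dir, "drug_grid.csv")
  utils::write.csv(grid[setdiff(names(grid), "drug")], p,
                   row.names = FALSE)
  c(paths, p)
}

#' Serialize / restore protocols
#'
#' Protocols round-trip losslessly through YAML (numbers written at full
#' precision).
#'
#' @param proto A [protocol()].
#' @param path File path.
#' @return The path (write) or a `protocol` (read).
#' @export
write_protocol_config <- function(proto, path) {
  # grid values serialized as full-precision strings so the round trip is
  # bit-exact (YAML float formatting loses the last bits)
  num <- function(x) sprintf("%.17g", x)
  yaml::write_yaml(list(
    name = proto$name, holding = proto$holding,
    segments = lapply(seq_len(nrow(proto$segments)), function(i) {
      list(voltage = num(proto$segments$voltage[i]),
           duration = num(proto$segments$duration[i]))
    }),
    sweep = list(segment = proto$sweep$segment, field = proto$sweep$field,
                 values = num(proto$sweep$values)),
    test_index = proto$test_index),
    path)
  invisible(path)
}

#' @rdname write_protocol_config
#' @export
read_protocol_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  segs <- tibble(
    voltage = vapply(cfg$segments, function(s) as.numeric(s$voltage),
                     numeric(1)),
    duration = vapply(cfg$segments, function(s) as.numeric(s$duration),
                      numeric(1)))
  protocol(cfg$name, cfg$holding, segs,
           list(segment = cfg$sweep$segment, field = cfg$sweep$field,
                values = as.numeric(unlist(cfg$sweep$values))),
           cfg$test_index)
}

#' Write a sweep result as tidy CSV with a JSON metadata sidecar
#'
#' @param result A `sweep_result` from [run_sweep()].
#' @param path CSV path; the sidecar is written next to it with a `.json`
#'   extension.
#' @param meta Extra metadata fields for the sidecar.
#' @return The CSV path, invisibly.
#' @export
write_sweep_result <- function(result, path, meta = list()) {
  utils::write.csv(
    result[c("sweep_value", "condition", "relative_current")], path,
    row.names = FALSE)
  sidecar <- c(list(
    protocol = attr(result, "protocol"),
    sweep_field = attr(result, "sweep_field"),
    normalization = attr(result, "normalization"),
    drug = attr(result, "drug"),
    result_hash = rlang::hash(
      result[c("sweep_value", "condition", "relative_current")])),
    meta)
  jsonlite::write_json(sidecar, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sweep_result
#' @export
read_sweep_result <- function(path) {
  df <- as_tibble(utils::read.csv(path))
  side <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  structure(df, class = c("sweep_result", class(df)),
            protocol = meta$protocol, sweep_field = meta$sweep_field,
            normalization = meta$normalization, drug = meta$drug)
}
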