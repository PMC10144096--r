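#' @title File formats: trajectory CSV, checkpoints, run manifests
#'
#' @description
#' Trajectories and measurements travel as headered CSV (one row per
#' frame: `frame, t, x, y, z` plus a `present` flag when gaps exist) so
#' they stay inspectable; model parameters travel as a JSON manifest plus
#' a raw little-endian binary tensor block, which round-trips doubles
#' bit-for-bit. Every artifact records the seed and a config digest so it
#' can be regenerated.
#'
#' @name cli-io
NULL

#' Write a trajectory / measurement sequence to CSV
#'
#' @param path Output file.
#' @param pos T x 3 matrix of positions (`NA` rows = gap frames).
#' @param t Optional vector of times (seconds); defaults to 0-based frame
#'   index.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(path, pos, t = NULL) {
  pos <- as.matrix(pos)
  stopifnot(ncol(pos) == 3)
  if (is.null(t)) t <- seq_len(nrow(pos)) - 1
  df <- data.frame(frame = seq_len(nrow(pos)), t = t,
                   x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   present = as.integer(!apply(pos, 1, anyNA)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory / measurement sequence from CSV
#'
#' Requires a header with at least `frame, t, x, y, z`; an optional
#' `present` column marks gap frames (which are returned as `NA` rows).
#' Malformed numeric fields raise a parse error naming the line.
#'
#' @param path Input file.
#' @return A list with `t` (times) and `pos` (T x 3, `NA` rows for gaps).
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path))
    stop_lstmkf(paste0("file not found: ", path), "lstmkf_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "t", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_lstmkf(paste0("missing column(s): ", paste(miss, collapse = ", ")),
                "lstmkf_parse_error")
  for (cn in c("t", "x", "y", "z")) {
    v <- df[[cn]]
    bad <- which(!is.na(v) & !is.numeric(v))
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & v != "NA")
      if (length(bad))
        stop_lstmkf(sprintf("non-numeric '%s' at line %d", cn, bad[1] + 1),
                    "lstmkf_parse_error")
      df[[cn]] <- conv
    }
  }
  pos <- unname(as.matrix(df[, c("x", "y", "z")]))
  if ("present" %in% names(df)) pos[df$present == 0, ] <- NA_real_
  list(t = df$t, pos = pos)
}

# pack a named list of numeric arrays into (manifest, raw doubles)
.pack_arrays <- function(arrays) {
  vals <- numeric(0)
  man <- list()
  off <- 0
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    man[[nm]] <- list(dim = if (is.null(dim(a))) length(a) else dim(a),
                      offset = off, length = length(a))
    vals <- c(vals, as.numeric(a))
    off <- off + length(a)
  }
  list(manifest = man, values = vals)
}

.unpack_arrays <- function(man, vals) {
  out <- list()
  for (nm in names(man)) {
    m <- man[[nm]]
    v <- vals[m$offset + seq_len(m$length)]
    dm <- unlist(m$dim)
    out[[nm]] <- if (length(dm) > 1) array(v, dm) else
      if (length(dm) == 1 && dm > 1 && m$length == dm) matrix(v, dm, 1) else v
    if (length(dm) == 2) out[[nm]] <- matrix(v, dm[1], dm[2])
  }
  out
}

#' Save a model checkpoint
#'
#' Writes `<path>.json` (class, configuration, tensor manifest, package
#' version) and `<path>.bin` (all parameter tensors as little-endian
#' doubles, bit-exact). Works for `lstmkf_model`, `std_lstm_model` and
#' optimizer states attached by training.
#'
#' @param model The model object.
#' @param path Path stem (no extension).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  arrays <- list()
  meta <- list(package_version = as.character(utils::packageVersion("lstmkf")))
  if (inherits(model, "lstmkf_model")) {
    meta$class <- "lstmkf_model"
    meta$cfg <- jsonlite::serializeJSON(model$cfg, digits = 17)
    arrays <- model$params
  } else if (inherits(model, "std_lstm_model")) {
    meta$class <- "std_lstm_model"
    meta$cfg <- jsonlite::serializeJSON(model$cfg, digits = 17)
    meta$d <- model$d
    arrays <- model$params
  } else {
    stop_lstmkf("unsupported checkpoint object", "lstmkf_invalid_parameter")
  }
  pk <- .pack_arrays(arrays)
  meta$tensors <- pk$manifest
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(pk$values, con, size = 8, endian = "little")
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path Path stem (no extension).
#' @return The reconstructed model object.
#' @export
load_checkpoint <- function(path) {
  jf <- paste0(path, ".json"); bf <- paste0(path, ".bin")
  if (!file.exists(jf) || !file.exists(bf))
    stop_lstmkf(paste0("checkpoint not found at ", path), "lstmkf_io_error")
  meta <- jsonlite::read_json(jf)
  n <- sum(vapply(meta$tensors, function(m) m$length, 0))
  con <- file(bf, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n, size = 8, endian = "little")
  params <- .unpack_arrays(meta$tensors, vals)
  cfg <- jsonlite::unserializeJSON(meta$cfg)
  if (meta$class == "lstmkf_model") {
    structure(list(cfg = cfg, params = params), class = "lstmkf_model")
  } else {
    structure(list(params = params, cfg = cfg, d = meta$d),
              class = "std_lstm_model")
  }
}

#' Digest of a configuration object
#'
#' MD5 of the canonical JSON serialization; recorded in run manifests so
#' outputs can be matched to the exact configuration that produced them.
#'
#' @param cfg Any serializable R object.
#' @return Hex digest string.
#' @export
config_digest <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::serializeJSON(cfg, digits = 17), tf)
  unname(tools::md5sum(tf))
}

#' Write a run manifest
#'
#' @param path Output JSON path.
#' @param cfg The run configuration object.
#' @param seed The seed used.
#' @param extra Optional named list of extra fields.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, cfg, seed, extra = list()) {
  man <- c(list(seed = seed, config_digest = config_digest(cfg),
                package_version = as.character(utils::packageVersion("lstmkf")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
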