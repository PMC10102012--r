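# Portable checkpoints: layer-name-keyed numeric arrays plus a config
# snapshot, stored as JSON. Array payloads are base64-encoded little-endian
# doubles so a save/load round trip is bit-identical (decimal text is not).

encode_array <- function(x) {
  list(dim = if (is.null(dim(x))) length(x) else dim(x),
       data = jsonlite::base64_enc(writeBin(as.vector(as.numeric(x)),
                                            raw(), size = 8L,
                                            endian = "little")))
}

decode_array <- function(obj) {
  d <- unlist(obj$dim)
  vals <- readBin(jsonlite::base64_dec(obj$data), "double",
                  n = prod(d), size = 8L, endian = "little")
  if (length(d) > 1L) dim(vals) <- d
  vals
}

#' Save a pretraining checkpoint to JSON
#' @param checkpoint A `cl_checkpoint` (see [pretrain()]).
#' @param path Output path.
#' @export
save_checkpoint <- function(checkpoint, path) {
  obj <- list(
    encoder_name = checkpoint$encoder_name,
    h_dim = checkpoint$h_dim,
    epoch = checkpoint$epoch,
    loss_trace = checkpoint$loss_trace,
    config = checkpoint$config_snapshot,
    encoder = lapply(checkpoint$encoder, encode_array),
    projection = lapply(checkpoint$projection, encode_array)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a pretraining checkpoint from JSON
#' @param path Path written by [save_checkpoint()].
#' @return A `cl_checkpoint`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path)
  structure(list(
    encoder = lapply(obj$encoder, decode_array),
    projection = lapply(obj$projection, decode_array),
    encoder_name = obj$encoder_name,
    h_dim = as.integer(obj$h_dim),
    epoch = as.integer(obj$epoch),
    loss_trace = as.numeric(unlist(obj$loss_trace)),
    config_snapshot = obj$config
  ), class = "cl_checkpoint")
}
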