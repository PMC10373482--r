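# Plain-text model checkpoints: the architecture configuration followed by
# every weight matrix, in a single readable archive.

#' Save a model checkpoint
#'
#' Writes the embedded configuration and all weight matrices to a plain
#' text archive re-readable by [load_model()].
#'
#' @param model An `xtal_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- model$config
  writeLines("xtalgnn-checkpoint 1", con)
  for (nm in names(cfg)) {
    writeLines(sprintf("config %s %s", nm, as.character(cfg[[nm]])), con)
  }
  for (nm in names(model$weights)) {
    w <- model$weights[[nm]]
    writeLines(sprintf("weight %s %d %d", nm, nrow(w), ncol(w)), con)
    writeLines(paste(format(as.vector(w), digits = 17, trim = TRUE,
                            scientific = TRUE), collapse = " "), con)
  }
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_model()].
#' @return An `xtal_model`.
#' @export
load_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1], "xtalgnn-checkpoint")) {
    stop("not a model checkpoint file")
  }
  cfg_raw <- list()
  weights <- list()
  i <- 2
  while (i <= length(lines)) {
    toks <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    if (toks[1] == "config") {
      cfg_raw[[toks[2]]] <- paste(toks[-(1:2)], collapse = " ")
      i <- i + 1
    } else if (toks[1] == "weight") {
      nr <- as.integer(toks[3]); nc <- as.integer(toks[4])
      vals <- as.numeric(strsplit(lines[i + 1], " ", fixed = TRUE)[[1]])
      weights[[toks[2]]] <- matrix(vals, nr, nc)
      i <- i + 2
    } else i <- i + 1
  }
  cfg <- model_config(
    n_gc = as.integer(cfg_raw$n_gc),
    node_width = as.integer(cfg_raw$node_width),
    message_width = as.integer(cfg_raw$message_width),
    edge_embed_width = as.integer(cfg_raw$edge_embed_width),
    n_basis = as.integer(cfg_raw$n_basis),
    dropout = as.numeric(cfg_raw$dropout),
    atomic_embedding_dim = as.integer(cfg_raw$atomic_embedding_dim),
    head = cfg_raw$head,
    inter_edge_mode = cfg_raw$inter_edge_mode,
    leaky_slope = as.numeric(cfg_raw$leaky_slope),
    seed = as.integer(cfg_raw$seed)
  )
  structure(list(config = cfg, weights = weights), class = "xtal_model")
}
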