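# Structure file I/O: SMILES lists, MDL MOL blocks and SDF files.
# SDF reading is delegated to ChemmineR; SMILES is parsed natively (the
# matcher needs kekulized bond orders and precise error positions).

#' Read and write SMILES files
#'
#' SMILES files have one structure per line, with an optional
#' tab-separated id in the second field. Lines that fail to parse raise an
#' error naming the line.
#'
#' @param path File path.
#' @return `read_smiles_file()`: a molecule-set tibble (`id`, `smiles`,
#'   with `input_smiles` preserving the raw text).
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  smi <- vapply(parts, `[[`, character(1), 1L)
  id <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L) parts[[i]][[2L]] else sprintf("mol%d", i)
  }, character(1))
  can <- vapply(seq_along(smi), function(i) {
    tryCatch(canonical_smiles(smi[i]),
             error = function(e) stop("line ", i, " of ", path, ": ",
                                      conditionMessage(e), call. = FALSE))
  }, character(1))
  out <- tibble::tibble(id = id, smiles = can, input_smiles = smi)
  attr(out, "provenance") <- "loaded"
  out
}

#' @rdname read_smiles_file
#' @param molecules A data frame with `id` and `smiles` columns.
#' @export
write_smiles_file <- function(molecules, path) {
  tb <- .as_mol_tbl(molecules)
  writeLines(paste(tb$smiles, tb$id, sep = "\t"), path)
  invisible(path)
}

#' Read SDF / MOL structure files
#'
#' `read_sdf_file()` reads a multi-record SDF file through ChemmineR and
#' converts each record to a canonical SMILES; `parse_molblock()` parses a
#' single MOL block given as text. Records that fail conversion are
#' reported via the `note` column rather than aborting.
#'
#' @param path SDF file path.
#' @return A tibble with `id`, `smiles`, `note`.
#' @export
read_sdf_file <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("reading SDF files requires the ChemmineR package", call. = FALSE)
  sdf <- ChemmineR::read.SDFset(path)
  n <- length(sdf)
  rows <- purrr::map(seq_len(n), function(i) {
    rec <- sdf[[i]]
    id <- tryCatch(ChemmineR::sdfid(sdf[i]), error = function(e) NA)
    if (is.null(id) || length(id) != 1L || is.na(id) || !nzchar(id))
      id <- sprintf("sdf%d", i)
    g <- tryCatch(.sdf_to_molgraph(rec), error = function(e) e)
    if (inherits(g, "error")) {
      tibble::tibble(id = as.character(id), smiles = NA_character_,
                     note = paste0("record ", i, ": ", conditionMessage(g)))
    } else {
      tibble::tibble(id = as.character(id), smiles = mol_to_smiles(g),
                     note = NA_character_)
    }
  })
  dplyr::bind_rows(rows)
}

.sdf_to_molgraph <- function(rec) {
  ab <- ChemmineR::atomblock(rec)
  bb <- ChemmineR::bondblock(rec)
  elem <- sub("_.*$", "", rownames(ab))
  if (is.null(dim(bb)) || nrow(bb) == 0L) {
    bond <- NULL
  } else {
    ord <- as.integer(bb[, 3L])
    if (any(ord == 4L))
      stop("aromatic (order 4) MOL bonds are not supported; supply a ",
           "kekulized structure", call. = FALSE)
    bond <- cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]), ord)
  }
  g <- molgraph(elem, bond)
  comps <- .components(g)
  if (length(comps) > 1L) {
    g <- .pick_component(lapply(comps, function(at) .subgraph_atoms(g, at)),
                         "largest", "MOL block")
  }
  g
}

#' @rdname read_sdf_file
#' @param text A MOL block as a single string or character vector of lines.
#' @param component See [parse_structure()].
#' @export
parse_molblock <- function(text, component = c("error", "largest", "all")) {
  component <- match.arg(component)
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  text <- sub("(\\$\\$\\$\\$).*$", "\\1", text)  # first record only
  if (!grepl("\\$\\$\\$\\$", text)) text <- paste0(text, "\n$$$$\n")
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(text, tf)
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("parsing MOL blocks requires the ChemmineR package", call. = FALSE)
  sdf <- suppressWarnings(ChemmineR::read.SDFset(tf))
  ab <- ChemmineR::atomblock(sdf[[1L]])
  bb <- ChemmineR::bondblock(sdf[[1L]])
  elem <- sub("_.*$", "", rownames(ab))
  bond <- if (is.null(dim(bb)) || nrow(bb) == 0L) NULL else {
    cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]), as.integer(bb[, 3L]))
  }
  g <- molgraph(elem, bond)
  comps <- .components(g)
  .pick_component(lapply(comps, function(at) .subgraph_atoms(g, at)),
                  component, "MOL block")
}

#' Write molecules to an SDF file
#'
#' Writes a V2000 SDF with zero 2-D coordinates (the model is purely
#' topological).
#'
#' @param molecules A data frame with `id` and `smiles` columns.
#' @param path Output path.
#' @export
write_sdf_file <- function(molecules, path) {
  tb <- .as_mol_tbl(molecules)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(tb))) {
    g <- parse_structure(tb$smiles[i], component = "largest")
    A <- heavy_atoms(g); m <- nrow(g$bond)
    lines <- c(
      tb$id[i], "  unbio", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", A, m),
      vapply(seq_len(A), function(a)
        sprintf("    0.0000    0.0000    0.0000 %-3s 0  0", g$elem[a]),
        character(1)),
      vapply(seq_len(m), function(r)
        sprintf("%3d%3d%3d  0", g$bond[r, 1L], g$bond[r, 2L], g$bond[r, 3L]),
        character(1)),
      "M  END", "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}
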