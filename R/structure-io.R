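#' Read a macromolecular structure into an atom table
#'
#' Parses PDB or mmCIF coordinate records (via bio3d) into a tidy atom table.
#' All models of a multi-model file are kept and indexed contiguously from 1.
#' When duplicate altloc records exist for an atom, the highest-occupancy copy
#' is retained (ties resolved in favour of altloc 'A'). Waters and hetero
#' atoms are preserved.
#'
#' @param path Path to a `.pdb`, `.ent`, `.cif` or `.mmcif` file.
#' @param format One of `"auto"` (default, by extension), `"pdb"`, `"cif"`.
#' @return A `hex_structure`: list with `atoms` (tibble: `model`, `record`,
#'   `atom_id`, `atom_name`, `element`, `resid`, `chain`, `resno`, `x`, `y`,
#'   `z`, `occupancy`, `altloc`), `n_models`, `source_format`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", tolower(path))) "cif" else "pdb"
  }
  if (format == "pdb") {
    txt <- readLines(path, warn = FALSE)
    nonblank <- txt[nzchar(trimws(txt))]
    if (length(nonblank) && !grepl("^END", utils::tail(nonblank, 1)[[1]])) {
      warn("structure file has no END record; parsing permissively")
    }
    pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                    verbose = FALSE),
                    error = function(e) abort(paste0("failed to parse PDB '", path, "': ",
                                                     conditionMessage(e))))
  } else {
    pdb <- tryCatch(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
                    error = function(e) abort(paste0("failed to parse mmCIF '", path, "': ",
                                                     conditionMessage(e))))
  }
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) abort(paste0("empty structure: ", path))
  n_models <- max(1L, nrow(pdb$xyz))
  base <- tibble(
    record = at$type,
    atom_name = trimws(at$elety),
    element = structure_element(at),
    resid = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = as.integer(at$resno),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt), "", at$alt)
  )
  models <- purrr::map(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    dplyr::bind_cols(tibble(model = m), base,
                     tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  })
  atoms <- bind_rows(models) %>%
    dedupe_altlocs() %>%
    group_by(.data$model) %>%
    mutate(atom_id = dplyr::row_number()) %>%
    ungroup() %>%
    select("model", "record", "atom_id", "atom_name", "element", "resid",
           "chain", "resno", "x", "y", "z", "occupancy", "altloc")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("non-finite coordinates in structure")
  }
  new_structure(atoms, n_models, toupper(format))
}

new_structure <- function(atoms, n_models = max(atoms$model), source_format = "PDB") {
  structure(list(atoms = as_tibble(atoms), n_models = as.integer(n_models),
                 source_format = source_format),
            class = "hex_structure")
}

#' @export
print.hex_structure <- function(x, ...) {
  cat(sprintf("<hex_structure> %d atoms, %d model(s), %d chain(s) [%s]\n",
              sum(x$atoms$model == 1), x$n_models,
              length(unique(x$atoms$chain)), x$source_format))
  invisible(x)
}

structure_element <- function(at) {
  el <- trimws(at$elesy)
  el[is.na(el)] <- ""
  miss <- !nzchar(el)
  if (any(miss)) {
    guess <- gsub("[^A-Za-z].*$", "", trimws(at$elety[miss]))
    two <- toupper(guess) %in% c("ZN", "CL", "BR", "NA", "MG", "FE", "CA", "MN", "CU")
    el[miss] <- ifelse(two, substr(guess, 1, 2), substr(guess, 1, 1))
  }
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
}

## Keep one altloc per atom: highest occupancy, ties in favour of 'A'.
dedupe_altlocs <- function(atoms) {
  atoms %>%
    mutate(.row = dplyr::row_number()) %>%
    group_by(.data$model, .data$chain, .data$resno, .data$resid, .data$atom_name) %>%
    arrange(dplyr::desc(.data$occupancy), .data$altloc != "A", .data$altloc,
            .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    arrange(.data$.row) %>%
    select(-".row")
}

## Accept either a hex_structure or a bare atom tibble everywhere downstream.
as_atoms <- function(x, model = NULL) {
  atoms <- if (inherits(x, "hex_structure")) x$atoms else as_tibble(x)
  req <- c("atom_name", "element", "resid", "chain", "resno", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols)) {
    abort(paste0("atom table lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"model" %in% names(atoms)) atoms$model <- 1L
  if (!"record" %in% names(atoms)) atoms$record <- "ATOM"
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (!is.null(model)) atoms <- filter(atoms, .data$model == !!model)
  atoms
}

#' Write an atom table as a PDB file
#'
#' @param structure A `hex_structure` or atom tibble (model 1 is written).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  at <- as_atoms(structure, model = 1L)
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = at$record,
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   elety = at$atom_name, o = at$occupancy,
                   b = rep(0, nrow(at)), elesy = at$element)
  invisible(path)
}

## Apply a rigid motion to every model of a structure/atom table.
#' Rigidly transform all atom coordinates
#'
#' @param structure A `hex_structure` or atom tibble.
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation Length-3 translation (Angstroms).
#' @return Object of the same kind with transformed coordinates.
#' @export
transform_structure <- function(structure, rotation = diag(3), translation = c(0, 0, 0)) {
  at <- as_atoms(structure)
  new_xyz <- transform_coords(as.matrix(at[, c("x", "y", "z")]), rotation, translation)
  at$x <- new_xyz[, 1]; at$y <- new_xyz[, 2]; at$z <- new_xyz[, 3]
  if (inherits(structure, "hex_structure")) {
    new_structure(at, structure$n_models, structure$source_format)
  } else {
    at
  }
}
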