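# File interchange: chains as JSON/CSV, coordinates as XYZ/PDB, potential
# grids as OpenDX scalar fields (APBS-compatible), plus the run-config
# sidecar. Coordinates are nm internally and Angstrom in PDB; grids are mV.

.valid_states <- c("OH", "CM", "CM8")

#' Write / read a chain as JSON
#'
#' Schema: `length`, `ds_cm`, `amide_fraction`, `seed`, and `sequence` as a
#' list of `pos2.pos3.pos6` state codes. Round trips losslessly.
#'
#' @param chain a `cmc_chain`.
#' @param path file path.
#' @return `write_chain_json`: the path, invisibly. `read_chain_json`: a
#'   `cmc_chain`.
#' @export
write_chain_json <- function(chain, path) {
  stopifnot(inherits(chain, "cmc_chain"))
  obj <- list(length = chain$N, ds_cm = chain$ds_cm,
              amide_fraction = chain$amide_fraction,
              enforce_exact_counts = chain$enforce_exact_counts,
              seed = chain$seed,
              sequence = apply(chain$states, 1, paste, collapse = "."))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_chain_json
#' @export
read_chain_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("length", "ds_cm", "amide_fraction", "sequence")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("chain JSON schema violation: missing field(s) ", paste(miss, collapse = ", "))
  parts <- strsplit(obj$sequence, ".", fixed = TRUE)
  bad <- which(lengths(parts) != 3 |
                 !vapply(parts, function(p) all(p %in% .valid_states), logical(1)))
  if (length(bad))
    stop("chain JSON schema violation: invalid state code at sequence entry ", bad[1],
         " ('", obj$sequence[bad[1]], "')")
  states <- do.call(rbind, parts)
  colnames(states) <- c("pos2", "pos3", "pos6")
  structure(list(states = states, N = as.integer(obj$length),
                 ds_cm = obj$ds_cm, amide_fraction = obj$amide_fraction,
                 enforce_exact_counts = isTRUE(obj$enforce_exact_counts),
                 seed = obj$seed),
            class = "cmc_chain")
}

#' Write / read a chain as flat CSV (one monomer per row)
#'
#' Columns: `index`, `pos2`, `pos3`, `pos6`. Chain-level parameters are not
#' carried by the CSV form; they can be supplied on read.
#'
#' @inheritParams write_chain_json
#' @param ds_cm,amide_fraction,seed parameters to attach on read.
#' @export
write_chain_csv <- function(chain, path) {
  stopifnot(inherits(chain, "cmc_chain"))
  df <- data.frame(index = seq_len(chain$N), chain$states)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_chain_csv
#' @export
read_chain_csv <- function(path, ds_cm = NA_real_, amide_fraction = NA_real_,
                           seed = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pos2", "pos3", "pos6")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("chain CSV schema violation: missing column(s) ", paste(miss, collapse = ", "))
  states <- as.matrix(df[, need])
  bad <- which(!(states %in% .valid_states))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(states))
    stop("chain CSV schema violation: invalid state '", states[bad[1]],
         "' at row ", rc[1], ", column ", need[rc[2]])
  }
  structure(list(states = states, N = nrow(states), ds_cm = ds_cm,
                 amide_fraction = amide_fraction,
                 enforce_exact_counts = NA, seed = seed),
            class = "cmc_chain")
}

# Flatten a conformer or packed system into an export table (nm).
.coord_table <- function(x) {
  if (inherits(x, "cmc_conformer")) {
    data.frame(
      x = c(x$backbone[, 1], x$charge_beads$x, x$alkyl_beads$x),
      y = c(x$backbone[, 2], x$charge_beads$y, x$alkyl_beads$y),
      z = c(x$backbone[, 3], x$charge_beads$z, x$alkyl_beads$z),
      type = c(rep("backbone", nrow(x$backbone)),
               rep("charge", nrow(x$charge_beads)),
               rep("alkyl", nrow(x$alkyl_beads))),
      chain = 1L)
  } else if (inherits(x, "packed_system")) {
    x$beads
  } else stop("cannot export coordinates from an object of class ", class(x)[1])
}

.bead_element <- c(backbone = "C", charge = "O", alkyl = "S")

#' Export coordinates as XYZ or PDB
#'
#' Bead element codes: backbone = C, charge bead = O, alkyl bead = S. XYZ is
#' written in nm at full precision; PDB in Angstrom at 3 decimals with
#' HETATM records and one chain ID per polymer.
#'
#' @param x a `cmc_conformer` or `packed_system`.
#' @param path output file.
#' @param format `"xyz"` or `"pdb"`.
#' @return the path, invisibly.
#' @export
export_coordinates <- function(x, path, format = c("xyz", "pdb")) {
  format <- match.arg(format)
  tb <- .coord_table(x)
  el <- .bead_element[tb$type]
  if (format == "xyz") {
    lines <- c(as.character(nrow(tb)),
               "cmcnano beads (nm): backbone=C charge=O alkyl=S",
               sprintf("%s %.9f %.9f %.9f", el, tb$x, tb$y, tb$z))
  } else {
    chain_ids <- c(LETTERS, letters, 0:9)
    cid <- chain_ids[(tb$chain - 1) %% length(chain_ids) + 1]
    lines <- character(nrow(tb))
    serial <- seq_len(nrow(tb))
    for (i in serial) {
      lines[i] <- sprintf(
        "HETATM%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i %% 100000, el[i], "BEA", cid[i], ((i - 1) %% 9999) + 1,
        tb$x[i] * 10, tb$y[i] * 10, tb$z[i] * 10, el[i])
    }
    lines <- c(lines, "END")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read coordinates written by [export_coordinates()]
#'
#' @param path file path.
#' @param format `"xyz"` (nm) or `"pdb"` (Angstrom, converted back to nm).
#' @return data.frame x, y, z (nm), element.
#' @export
read_coordinates <- function(path, format = c("xyz", "pdb")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "xyz") {
    n <- as.integer(lines[1])
    if (n == 0)
      return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        element = character(0)))
    toks <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
    data.frame(x = as.numeric(vapply(toks, `[`, "", 2)),
               y = as.numeric(vapply(toks, `[`, "", 3)),
               z = as.numeric(vapply(toks, `[`, "", 4)),
               element = vapply(toks, `[`, "", 1))
  } else {
    at <- lines[startsWith(lines, "HETATM") | startsWith(lines, "ATOM")]
    data.frame(x = as.numeric(substr(at, 31, 38)) / 10,
               y = as.numeric(substr(at, 39, 46)) / 10,
               z = as.numeric(substr(at, 47, 54)) / 10,
               element = trimws(substr(at, 77, 78)))
  }
}

#' Export / import a potential grid in OpenDX scalar format
#'
#' Writes the APBS-compatible regular-grid OpenDX layout (`gridpositions`,
#' `gridconnections`, rank-0 data array in z-fastest order). Grids containing
#' non-finite values are rejected.
#'
#' @param grid a `potential_grid`.
#' @param path file path.
#' @return `export_grid_dx`: the path, invisibly. `read_grid_dx`: a
#'   `potential_grid` (physical parameters beyond geometry/values are not
#'   stored in DX and come back as `NA`).
#' @export
export_grid_dx <- function(grid, path) {
  stopifnot(inherits(grid, "potential_grid"))
  if (any(!is.finite(grid$values)))
    stop("grid contains non-finite values; refusing to export")
  d <- grid$dim
  # z-fastest (APBS) ordering
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))
  n <- length(vals)
  pad <- c(vals, rep(NA_real_, (3 - n %% 3) %% 3))
  rows <- matrix(pad, ncol = 3, byrow = TRUE)
  data_lines <- apply(rows, 1, function(r)
    paste(sprintf("%.6e", r[!is.na(r)]), collapse = " "))
  lines <- c(
    "# OpenDX scalar field written by cmcnano (potential, mV; lengths, nm)",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6e %.6e %.6e", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6e 0.000000e+00 0.000000e+00", grid$spacing),
    sprintf("delta 0.000000e+00 %.6e 0.000000e+00", grid$spacing),
    sprintf("delta 0.000000e+00 0.000000e+00 %.6e", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n),
    data_lines,
    'attribute "dep" string "positions"',
    'object "regular positions regular connections" class field',
    'component "positions" value 1',
    'component "connections" value 2',
    'component "data" value 3')
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname export_grid_dx
#' @export
read_grid_dx <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  gp <- grep("class gridpositions", lines, value = TRUE)[1]
  counts <- as.integer(strsplit(sub(".*counts ", "", gp), "\\s+")[[1]])
  org <- as.numeric(strsplit(sub("^origin\\s+", "",
                                 grep("^origin", lines, value = TRUE)[1]),
                             "\\s+")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  dmat <- t(vapply(deltas, function(l)
    as.numeric(strsplit(sub("^delta\\s+", "", l), "\\s+")[[1]]), numeric(3)))
  spacing <- unname(dmat[1, 1])
  i0 <- grep("data follows", lines)
  i1 <- grep("^attribute", lines)[1]
  vals <- as.numeric(unlist(strsplit(trimws(lines[(i0 + 1):(i1 - 1)]), "\\s+")))
  arr <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  structure(list(origin = org, spacing = spacing, dim = counts,
                 values = arr, eps_r = NA_real_, ionic_strength = NA_real_,
                 temperature = NA_real_, lambda_d = NA_real_, cap = NA_real_,
                 charges = data.frame(x = numeric(0), y = numeric(0),
                                      z = numeric(0), q = numeric(0))),
            class = "potential_grid")
}
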