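# Multi-model PDB and multi-frame XYZ I/O for conformer pools.
#
# PDB dialect: only MODEL / ATOM / HETATM / ENDMDL records are interpreted.
# Element is taken from columns 77-78, falling back to the leading letter(s)
# of the atom name. Coordinates are written with the standard %8.3f fields,
# so a read -> write -> read round trip preserves them to 3 decimals.

.pdb_field <- function(line, from, to) {
  n <- nchar(line)
  if (n < from) return("")
  trimws(substr(line, from, min(to, n)))
}

.element_from_name <- function(name) {
  # strip digits/primes, keep leading letters; two-letter symbols we expect
  letters_only <- gsub("[^A-Za-z]", "", name)
  two <- toupper(substr(letters_only, 1, 2))
  if (two %in% c("BR", "CL")) {
    return(paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))))
  }
  toupper(substr(letters_only, 1, 1))
}

.parse_pdb_models <- function(lines) {
  models <- list()
  cur <- NULL
  in_model <- FALSE
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    rec <- toupper(.pdb_field(line, 1, 6))
    if (rec == "MODEL") {
      cur <- list()
      in_model <- TRUE
    } else if (rec == "ENDMDL") {
      if (!in_model) {
        stop("format error at line ", ln, ": ENDMDL without MODEL",
             call. = FALSE)
      }
      models[[length(models) + 1]] <- cur
      cur <- NULL
      in_model <- FALSE
    } else if (rec %in% c("ATOM", "HETATM")) {
      if (!in_model) {
        # single-model file without MODEL records
        cur <- if (is.null(cur)) list() else cur
        in_model <- NA # mark implicit model
      }
      x <- suppressWarnings(as.numeric(.pdb_field(line, 31, 38)))
      y <- suppressWarnings(as.numeric(.pdb_field(line, 39, 46)))
      z <- suppressWarnings(as.numeric(.pdb_field(line, 47, 54)))
      resno <- suppressWarnings(as.integer(.pdb_field(line, 23, 26)))
      if (anyNA(c(x, y, z)) || is.na(resno)) {
        stop("format error at line ", ln, ": unparseable ATOM record",
             call. = FALSE)
      }
      elem <- .pdb_field(line, 77, 78)
      name <- .pdb_field(line, 13, 16)
      if (!nzchar(elem)) elem <- .element_from_name(name)
      # normalize PDB upper-case symbols to title case (BR -> Br)
      elem <- paste0(toupper(substr(elem, 1, 1)),
                     tolower(substr(elem, 2, nchar(elem))))
      cur[[length(cur) + 1]] <- list(
        name = name, element = elem, res_index = resno,
        res_name = .pdb_field(line, 18, 20), xyz = c(x, y, z))
    }
  }
  if (!is.null(cur)) models[[length(models) + 1]] <- cur
  if (length(models) == 0) {
    stop("format error: no ATOM records found", call. = FALSE)
  }
  models
}

.model_to_conformer <- function(atoms, id, labels = character()) {
  conformer(
    id = id,
    atoms = data.frame(
      name = vapply(atoms, `[[`, character(1), "name"),
      element = vapply(atoms, `[[`, character(1), "element"),
      res_index = vapply(atoms, `[[`, integer(1), "res_index"),
      res_name = vapply(atoms, `[[`, character(1), "res_name"),
      stringsAsFactors = FALSE),
    xyz = do.call(rbind, lapply(atoms, `[[`, "xyz")),
    labels = labels)
}

.parse_xyz_frames <- function(lines) {
  frames <- list()
  i <- 1
  n_lines <- length(lines)
  while (i <= n_lines) {
    if (!nzchar(trimws(lines[[i]]))) {
      i <- i + 1
      next
    }
    n <- suppressWarnings(as.integer(trimws(lines[[i]])))
    if (is.na(n) || n <= 0) {
      stop("format error at line ", i, ": expected atom count", call. = FALSE)
    }
    if (i + 1 + n > n_lines) {
      stop("format error at line ", i, ": truncated XYZ frame", call. = FALSE)
    }
    comment <- trimws(lines[[i + 1]])
    atoms <- vector("list", n)
    for (k in seq_len(n)) {
      ln <- i + 1 + k
      parts <- strsplit(trimws(lines[[ln]]), "\\s+")[[1]]
      if (length(parts) < 4) {
        stop("format error at line ", ln, ": unparseable XYZ record",
             call. = FALSE)
      }
      xyz <- suppressWarnings(as.numeric(parts[2:4]))
      if (anyNA(xyz)) {
        stop("format error at line ", ln, ": unparseable coordinates",
             call. = FALSE)
      }
      atoms[[k]] <- list(name = parts[[1]], element = parts[[1]],
                         res_index = 1L, res_name = "UNK", xyz = xyz)
    }
    frames[[length(frames) + 1]] <- list(atoms = atoms, comment = comment)
    i <- i + 2 + n
  }
  if (length(frames) == 0) {
    stop("format error: empty XYZ file", call. = FALSE)
  }
  frames
}

#' Read a conformer pool from a multi-model PDB or multi-frame XYZ file
#'
#' PDB models are delimited by MODEL/ENDMDL records (a file without MODEL
#' records is read as a single conformer); XYZ frames are concatenated
#' count/comment/atom blocks. All models must share one topology.
#'
#' @param path File path.
#' @param format `"pdb"` or `"xyz"`; default guesses from the extension.
#' @return A [conformer_pool]. Conformer ids are taken from XYZ comment
#'   lines when they look like `id=<...>`, otherwise `model_1`, `model_2`,
#'   ... Labels are restored from `labels=<a|b>` tags written by
#'   [write_conformer_pool()].
#' @export
read_conformer_pool <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") {
    models <- .parse_pdb_models(lines)
    meta <- .read_pool_meta(lines)
    confs <- lapply(seq_along(models), function(k) {
      id <- if (!is.null(meta) && k <= length(meta$ids)) meta$ids[[k]]
            else paste0("model_", k)
      labels <- if (!is.null(meta)) meta$labels[[k]] else character()
      .model_to_conformer(models[[k]], id, labels)
    })
  } else {
    frames <- .parse_xyz_frames(lines)
    confs <- lapply(seq_along(frames), function(k) {
      cm <- frames[[k]]$comment
      id <- if (grepl("id=\\S+", cm)) sub(".*id=(\\S+).*", "\\1", cm)
            else paste0("model_", k)
      labels <- if (grepl("labels=\\S+", cm)) {
        tag <- sub(".*labels=(\\S+).*", "\\1", cm)
        strsplit(tag, "\\|")[[1]]
      } else character()
      .model_to_conformer(frames[[k]]$atoms, id, labels)
    })
  }
  ref <- confs[[1]]
  for (k in seq_along(confs)) {
    if (nrow(confs[[k]]$atoms) != nrow(ref$atoms)) {
      stop("topology error: model ", k, " has ", nrow(confs[[k]]$atoms),
           " atoms, expected ", nrow(ref$atoms), call. = FALSE)
    }
  }
  conformer_pool(confs)
}

# Conformer ids/labels are carried in REMARK 250 lines so that a
# write -> read round trip preserves them.
.read_pool_meta <- function(lines) {
  rem <- grep("^REMARK 250 CONFORMER ", lines, value = TRUE)
  if (length(rem) == 0) return(NULL)
  ids <- character(length(rem))
  labels <- vector("list", length(rem))
  for (k in seq_along(rem)) {
    parts <- strsplit(trimws(sub("^REMARK 250 CONFORMER ", "", rem[[k]])),
                      "\\s+")[[1]]
    ids[[k]] <- parts[[2]]
    labels[[k]] <- if (length(parts) >= 3 && nzchar(parts[[3]])) {
      strsplit(parts[[3]], "\\|")[[1]]
    } else character()
  }
  list(ids = ids, labels = labels)
}

#' Write a conformer pool to a multi-model PDB or multi-frame XYZ file
#'
#' @param pool A [conformer_pool].
#' @param path Output file path.
#' @param format `"pdb"` or `"xyz"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_conformer_pool <- function(pool, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  out <- character()
  if (format == "pdb") {
    for (k in seq_len(length(pool))) {
      cf <- pool[[k]]
      out <- c(out, sprintf("REMARK 250 CONFORMER %d %s %s", k, cf$id,
                            paste(cf$labels, collapse = "|")))
    }
    for (k in seq_len(length(pool))) {
      cf <- pool[[k]]
      out <- c(out, sprintf("MODEL     %4d", k))
      for (i in seq_len(nrow(cf$atoms))) {
        a <- cf$atoms[i, ]
        nm <- if (nchar(a$name) < 4) paste0(" ", a$name) else a$name
        out <- c(out, sprintf(
          "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          i, nm, a$res_name, a$res_index,
          cf$xyz[i, 1], cf$xyz[i, 2], cf$xyz[i, 3], toupper(a$element)))
      }
      out <- c(out, "ENDMDL")
    }
    out <- c(out, "END")
  } else {
    for (k in seq_len(length(pool))) {
      cf <- pool[[k]]
      out <- c(out, as.character(nrow(cf$atoms)),
               paste0("id=", cf$id,
                      if (length(cf$labels))
                        paste0(" labels=", paste(cf$labels, collapse = "|"))
                      else ""))
      out <- c(out, sprintf("%-2s %12.6f %12.6f %12.6f",
                            cf$atoms$element, cf$xyz[, 1], cf$xyz[, 2],
                            cf$xyz[, 3]))
    }
  }
  writeLines(out, path)
  invisible(path)
}
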