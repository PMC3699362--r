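#' Read a TPS landmark file
#'
#' Parses the plain-text TPS format used by the tps series of
#' geometric-morphometrics programs.  Each record starts with an `LM=k`
#' line followed by `k` lines of whitespace-separated x y coordinates,
#' optionally followed by `ID=`, `IMAGE=` and `SCALE=` lines.  When a
#' `SCALE=` line is present the stored coordinates are multiplied by it, so
#' the returned coordinates are always in physical units.  `CURVES=` /
#' `POINTS=` blocks (outline curves) are skipped with a warning, since only
#' fixed landmarks and flagged semilandmarks are analysed downstream.
#'
#' Coordinates are taken as 2D Cartesian with y pointing up; no image-row
#' flipping is applied.  If the digitiser used image (y-down) coordinates,
#' flip before analysis.
#'
#' @param path Path to a TPS file.
#' @return A list of `tps_record` objects, each with elements
#'   `coords` (k x 2 numeric matrix, physical units), `id` (character),
#'   `scale` (numeric or `NA`).
#' @seealso [write_tps()]
#' @export
read_tps <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  records <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      stop("malformed TPS file: expected 'LM=' line at line ", i,
           ", got: ", lines[i])
    }
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", lines[i],
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 0) stop("malformed landmark-count line: ", lines[i])
    i <- i + 1L
    coords <- matrix(NA_real_, nrow = k, ncol = 2)
    for (j in seq_len(k)) {
      if (i > n || grepl("^[A-Za-z]+\\s*=", lines[i])) {
        stop("TPS record declares ", k, " landmarks but has only ",
             j - 1L, " coordinate lines")
      }
      xy <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1]]))
      if (length(xy) != 2L || anyNA(xy)) {
        stop("malformed coordinate line in TPS file: ", lines[i])
      }
      coords[j, ] <- xy
      i <- i + 1L
    }
    id <- NA_character_
    scale <- NA_real_
    # trailing keyword lines for this record
    while (i <= n && !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      ln <- lines[i]
      if (grepl("^ID\\s*=", ln, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", ln, ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", ln, ignore.case = TRUE)) {
        scale <- as.numeric(sub("^SCALE\\s*=\\s*", "", ln, ignore.case = TRUE))
        if (is.na(scale) || scale <= 0) stop("SCALE must be a positive number")
      } else if (grepl("^(CURVES|POINTS)\\s*=", ln, ignore.case = TRUE)) {
        warning("TPS CURVES/POINTS block ignored (only fixed landmarks are read)")
      } else if (grepl("^IMAGE\\s*=", ln, ignore.case = TRUE)) {
        # carried for provenance only
      } else if (grepl("^[A-Za-z]+\\s*=", ln)) {
        # unknown keyword line: ignore
      } else {
        stop("unexpected line in TPS file: ", ln)
      }
      i <- i + 1L
    }
    if (!is.na(scale)) coords <- coords * scale
    rec <- structure(list(coords = coords, id = id, scale = scale),
                     class = "tps_record")
    records[[length(records) + 1L]] <- rec
  }
  records
}

#' Write landmark records to a TPS file
#'
#' Inverse of [read_tps()].  Coordinates are written in physical units with
#' no `SCALE=` line (scale already applied), at 10 significant digits, so a
#' read/write round trip is lossless at that precision.
#'
#' @param records List of `tps_record` objects, or bare k x 2 matrices.
#' @param path Output path.
#' @export
write_tps <- function(records, path) {
  out <- character(0)
  for (rec in records) {
    if (is.matrix(rec)) rec <- list(coords = rec, id = NA_character_)
    coords <- rec$coords
    out <- c(out, sprintf("LM=%d", nrow(coords)),
             sprintf("%.10g %.10g", coords[, 1], coords[, 2]))
    if (!is.null(rec$id) && !is.na(rec$id)) {
      out <- c(out, paste0("ID=", rec$id))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a phylogeny from Newick text or file
#'
#' Thin validating wrapper over [ape::read.tree()].  Requires unique tip
#' labels and a branch length on every non-root edge; records whether the
#' tree is fully bifurcating.  Unlabelled internal nodes are allowed and a
#' root edge length, if present, is ignored (as `ape` does).
#'
#' @param x Path to a Newick file, or a Newick string.
#' @return An `ape` `phylo` object with an added logical attribute
#'   `bifurcating`.
#' @export
read_newick <- function(x) {
  tr <- if (length(x) == 1L && grepl("[(;]", x)) {
    ape::read.tree(text = x)
  } else {
    stopifnot(file.exists(x))
    ape::read.tree(x)
  }
  if (is.null(tr)) stop("could not parse Newick input")
  validate_phylogeny(tr)
}

#' Validate a phylo object for use in the pipeline
#'
#' @param tr An `ape` `phylo` object.
#' @return The tree, with attribute `bifurcating` set.
#' @export
validate_phylogeny <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a 'phylo' object")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  if (is.null(tr$edge.length)) {
    stop("tree has no branch lengths; every non-root edge needs one")
  }
  if (anyNA(tr$edge.length)) stop("missing branch length on a non-root edge")
  if (any(tr$edge.length < 0)) stop("negative branch length")
  attr(tr, "bifurcating") <- ape::is.rooted(tr) && ape::is.binary(tr)
  tr
}

#' Write a phylogeny to Newick
#'
#' @param tr A `phylo` object.
#' @param path Output path; if `NULL`, the Newick string is returned.
#' @export
write_newick <- function(tr, path = NULL) {
  if (is.null(path)) return(ape::write.tree(tr))
  ape::write.tree(tr, file = path)
  invisible(path)
}

#' Read a per-taxon trait table
#'
#' Expects a UTF-8 CSV with header and at least the columns `taxon`, `wing`
#' (`"fore"` or `"hind"`), `coloration_group` (integer 1-6).  Optional
#' columns (`n_specimens`, `rsm_mean`, `log_centroid_size_mean`) are passed
#' through.  One row per taxon x wing; the coloration group may legitimately
#' differ between the fore- and hindwing of the same taxon.
#'
#' @param path CSV path.
#' @return A data.frame of validated trait records (zero rows for an empty
#'   file with a header, or a file with no content).
#' @export
read_trait_table <- function(path) {
  stopifnot(file.exists(path))
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    return(data.frame(taxon = character(0), wing = character(0),
                      coloration_group = integer(0)))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_trait_table(df)
}

#' Validate a trait table
#' @param df data.frame with columns taxon, wing, coloration_group.
#' @return The validated data.frame.
#' @export
validate_trait_table <- function(df) {
  need <- c("taxon", "wing", "coloration_group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trait table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(df)
  if (!all(df$wing %in% c("fore", "hind"))) {
    stop("wing must be 'fore' or 'hind'")
  }
  g <- df$coloration_group
  if (!all(g == as.integer(g)) || any(g < 1L | g > 6L)) {
    stop("coloration_group must be an integer in 1..6")
  }
  df$coloration_group <- as.integer(g)
  if (anyDuplicated(df[, c("taxon", "wing")])) {
    stop("duplicate taxon x wing rows in trait table")
  }
  df
}

#' Write a trait table to CSV
#' @param df data.frame as returned by [read_trait_table()].
#' @param path Output path.
#' @export
write_trait_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a wing outline from CSV
#'
#' The outline CSV has columns `x`, `y` and an optional `role` column
#' marking one vertex `base` and one `apex`.  Vertices are an ordered simple
#' polygon in physical units.
#'
#' @param path CSV path.
#' @return A `wing_outline` object (see [wing_outline()]).
#' @export
read_outline_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("x", "y", "role") %in% names(df)))
  b <- which(df$role == "base")
  a <- which(df$role == "apex")
  if (length(b) != 1L || length(a) != 1L) {
    stop("outline CSV must mark exactly one 'base' and one 'apex' row")
  }
  verts <- cbind(df$x, df$y)[df$role == "vertex", , drop = FALSE]
  wing_outline(verts, base = c(df$x[b], df$y[b]),
               apex = c(df$x[a], df$y[a]))
}

#' Write a wing outline to CSV
#'
#' Polygon vertices get `role = "vertex"`; the base and apex points (which
#' need not be vertices) get their own rows.
#'
#' @param outline A `wing_outline`.
#' @param path Output path.
#' @export
write_outline_csv <- function(outline, path) {
  v <- outline$vertices
  df <- data.frame(x = c(v[, 1], outline$base[1], outline$apex[1]),
                   y = c(v[, 2], outline$base[2], outline$apex[2]),
                   role = c(rep("vertex", nrow(v)), "base", "apex"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
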