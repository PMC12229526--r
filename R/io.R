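# File formats: long-format CSV tables for replicate calls, sex markers
# and haplotypes; GeoJSON boundaries/transects; ESRI ASCII altitude
# grids; GenePop export of an individual catalog.

#' Read the long-format replicate call table
#'
#' Expected columns: `sample_id`, `site`, `x`, `y`, `visit`, `locus`,
#' `replicate`, `allele1`, `allele2` (empty / NA = failed amplification).
#' @param path CSV file.
#' @export
read_replicates_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "locus", "replicate", "allele1", "allele2")
  if (!all(need %in% names(df)))
    stop(sprintf("invalid-data: replicates table lacks columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  df$allele1 <- as.character(df$allele1)
  df$allele2 <- as.character(df$allele2)
  df$allele1[df$allele1 %in% c("", "NA")] <- NA
  df$allele2[df$allele2 %in% c("", "NA")] <- NA
  df
}

#' Write the simulated study tables to CSV files
#'
#' Writes `replicates.csv`, `sex_markers.csv`, `haplotypes.csv`,
#' `samples.csv` and `truth.csv` (per-individual activity centres,
#' inclusion flags, sexes, and the detection-to-identity mapping) in the
#' schemas the analysis pipeline reads.
#'
#' @param study a [simulate_study()] bundle.
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths written.
#' @export
write_study_csv <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    replicates = file.path(dir, "replicates.csv"),
    sex_markers = file.path(dir, "sex_markers.csv"),
    haplotypes = file.path(dir, "haplotypes.csv"),
    samples = file.path(dir, "samples.csv"),
    truth = file.path(dir, "truth.csv"))
  samples <- study$samples
  reps <- merge(study$genotypes$replicates,
                samples[, c("sample_id", "site", "x", "y", "visit")],
                by = "sample_id", sort = FALSE)
  write.csv(reps, paths["replicates"], row.names = FALSE)
  write.csv(study$genotypes$sex_markers, paths["sex_markers"], row.names = FALSE)
  write.csv(study$genotypes$haplotypes, paths["haplotypes"], row.names = FALSE)
  write.csv(samples, paths["samples"], row.names = FALSE)
  truth_rows <- list()
  for (nm in setdiff(names(study), c("samples", "genotypes", "seed"))) {
    pop <- study[[nm]]$population$individuals
    pop$site <- nm
    truth_rows[[nm]] <- pop
  }
  write.csv(do.call(rbind, truth_rows), paths["truth"], row.names = FALSE)
  invisible(paths)
}

#' Export an individual catalog in GenePop format
#'
#' Two-digit-coded alleles per locus, one population block per site.
#' Allele labels are recoded to ranks within locus; the mapping is
#' returned invisibly.
#'
#' @param catalog an `individual_catalog`.
#' @param path output text file.
#' @param title first header line.
#' @export
write_genepop <- function(catalog, path, title = "gnisscr catalog export") {
  g <- catalog$genotypes
  loci <- catalog$loci
  maps <- lapply(loci, function(l) {
    al <- sort(unique(stats::na.omit(c(g$allele1[g$locus == l],
                                       g$allele2[g$locus == l]))))
    setNames(sprintf("%02d", seq_along(al)), al)
  })
  names(maps) <- loci
  lines <- c(title, loci)
  inds <- catalog$individuals
  sites <- unique(inds$site)
  if (all(is.na(sites))) { sites <- "all"; inds$site <- "all" }
  for (st in sites) {
    lines <- c(lines, "POP")
    for (id in inds$individual_id[inds$site %in% st]) {
      codes <- vapply(loci, function(l) {
        r <- g[g$individual_id == id & g$locus == l, ]
        if (!nrow(r) || is.na(r$allele1[1])) return("0000")
        paste0(maps[[l]][r$allele1[1]], maps[[l]][r$allele2[1]])
      }, character(1))
      lines <- c(lines, paste0("ind_", id, " ,  ", paste(codes, collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(maps)
}

#' Read a GeoJSON Polygon or MultiLineString geometry
#'
#' Minimal reader for the two geometry types the pipeline consumes:
#' returns the first polygon's outer ring as a vertex matrix, or a list
#' of polyline coordinate matrices. Coordinates must already be projected
#' (planar metres).
#'
#' @param path GeoJSON file.
#' @return for polygons, an n x 2 matrix; for line features, a list of
#'   matrices.
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = TRUE)
  geoms <- if (identical(gj$type, "FeatureCollection")) {
    if (is.data.frame(gj$features)) {
      lapply(seq_len(nrow(gj$features)), function(i)
        list(type = gj$features$geometry$type[i],
             coordinates = gj$features$geometry$coordinates[[i]]))
    } else lapply(gj$features, function(f) f$geometry)
  } else if (identical(gj$type, "Feature")) list(gj$geometry) else list(gj)
  out <- list()
  for (g in geoms) {
    if (g$type == "Polygon") {
      ring <- g$coordinates
      if (is.list(ring)) ring <- ring[[1]]
      if (length(dim(ring)) == 3) ring <- ring[1, , ]
      return(matrix(as.numeric(ring), ncol = 2))
    } else if (g$type %in% c("LineString", "MultiLineString")) {
      cc <- g$coordinates
      if (g$type == "LineString")
        out[[length(out) + 1]] <- matrix(as.numeric(cc), ncol = 2)
      else {
        if (is.list(cc)) for (l in cc)
          out[[length(out) + 1]] <- matrix(as.numeric(l), ncol = 2)
        else if (length(dim(cc)) == 3)
          for (i in seq_len(dim(cc)[1]))
            out[[length(out) + 1]] <- matrix(as.numeric(cc[i, , ]), ncol = 2)
      }
    }
  }
  if (!length(out)) stop("invalid-data: no supported geometry in GeoJSON")
  out
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file.
#' @return list of class `esri_grid`: `x`, `y` (cell-centre coordinate
#'   vectors, west to east / south to north), `values` (matrix indexed
#'   `[y, x]`), `cellsize`, `nodata`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list(); i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  ncols <- hdr$ncols; nrows <- hdr$nrows; cs <- hdr$cellsize
  xll <- hdr$xllcorner %||% (hdr$xllcenter - cs / 2)
  yll <- hdr$yllcorner %||% (hdr$yllcenter - cs / 2)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m <- m[nrows:1, , drop = FALSE]   # store south-to-north
  nodata <- hdr$nodata_value %||% -9999
  m[m == nodata] <- NA
  structure(list(
    x = xll + cs * (seq_len(ncols) - 0.5),
    y = yll + cs * (seq_len(nrows) - 0.5),
    values = m,      # indexed [y, x], rows south to north
    cellsize = cs, nodata = nodata), class = "esri_grid")
}

#' Write an ESRI ASCII grid
#' @param grid an `esri_grid` (see [read_esri_ascii()]); `values` indexed
#'   `[y, x]` south-to-north.
#' @param path output path.
#' @export
write_esri_ascii <- function(grid, path) {
  vals <- grid$values
  nr <- length(grid$y); nc <- length(grid$x)
  cs <- grid$cellsize
  m <- vals
  m[is.na(m)] <- grid$nodata %||% -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", nc), paste("nrows", nr),
    paste("xllcorner", min(grid$x) - cs / 2),
    paste("yllcorner", min(grid$y) - cs / 2),
    paste("cellsize", cs),
    paste("NODATA_value", grid$nodata %||% -9999)), con)
  for (r in nr:1)
    writeLines(paste(m[r, ], collapse = " "), con)
  invisible(path)
}

#' Build an in-memory raster from a function
#'
#' Utility for tests and simulations: evaluates `f(x, y)` on a regular
#' raster covering the rectangle.
#' @param f function of (x, y).
#' @param xlim,ylim extents (m).
#' @param cellsize raster resolution (m), default 2.
#' @export
raster_from_function <- function(f, xlim, ylim, cellsize = 2) {
  x <- seq(xlim[1] + cellsize / 2, xlim[2], by = cellsize)
  y <- seq(ylim[1] + cellsize / 2, ylim[2], by = cellsize)
  vals <- outer(y, x, function(yy, xx) {
    v <- f(xx, yy)
    if (length(v) == 1) rep(v, length(xx)) else v
  })
  structure(list(x = x, y = y, values = vals, cellsize = cellsize,
                 nodata = -9999), class = "esri_grid")
}
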