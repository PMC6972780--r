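#' Construct a multi-year land-cover stack
#'
#' Integer class codes per cell per year (e.g. IGBP classes from an annual
#' land-cover product), `NA` for nodata.
#'
#' @param values 3-d integer array `[row, col, year]`.
#' @param codebook Optional named character vector mapping class code to
#'   label; every observed code must appear in it when supplied.
#' @return An object of class `landcover_stack`.
#' @export
landcover_stack <- function(values, codebook = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  obs <- unique(values[!is.na(values)])
  if (any(obs != floor(obs))) stop("class codes must be integers", call. = FALSE)
  if (!is.null(codebook)) {
    missing_codes <- setdiff(obs, as.numeric(names(codebook)))
    if (length(missing_codes)) {
      stop("observed class codes absent from codebook: ",
           paste(missing_codes, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(values = values, codebook = codebook),
            class = "landcover_stack")
}

#' Default codebook for the 17 IGBP land-cover classes
#'
#' @return Named character vector, names are the class codes `0:16`.
#' @export
igbp_codebook <- function() {
  c(`0` = "water",
    `1` = "evergreen needleleaf forest",
    `2` = "evergreen broadleaf forest",
    `3` = "deciduous needleleaf forest",
    `4` = "deciduous broadleaf forest",
    `5` = "mixed forest",
    `6` = "closed shrublands",
    `7` = "open shrublands",
    `8` = "woody savannas",
    `9` = "savannas",
    `10` = "grasslands",
    `11` = "permanent wetlands",
    `12` = "croplands",
    `13` = "urban and built-up",
    `14` = "cropland/natural mosaic",
    `15` = "snow and ice",
    `16` = "barren or sparsely vegetated")
}

#' Land-cover classes treated as suitable moose habitat
#'
#' Forest, open shrubland, woody savanna and permanent wetland classes
#' (IGBP codes 1, 2, 3, 4, 5, 7, 8, 11).
#'
#' @return Integer vector of class codes.
#' @export
suitable_classes_default <- function() c(1L, 2L, 3L, 4L, 5L, 7L, 8L, 11L)

#' Derive the stable land-cover map from a multi-year stack
#'
#' A cell is assigned the class observed there in strictly more than half of
#' the years; cells where no class reaches that majority (including ties at
#' exactly half) are nodata. Nodata years count toward the denominator.
#'
#' @param stack A [landcover_stack()].
#' @return Integer matrix `[row, col]` of stable class codes, `NA` where no
#'   class is stable.
#' @export
stable_landcover <- function(stack) {
  stopifnot(inherits(stack, "landcover_stack"))
  d <- dim(stack$values)
  if (d[3] < 1L) stop("empty land-cover stack", call. = FALSE)
  npix <- d[1] * d[2]
  m <- matrix(stack$values, nrow = npix)  # pixels x years
  classes <- sort(unique(m[!is.na(m)]))
  if (length(classes) == 0L) return(matrix(NA_integer_, d[1], d[2]))
  counts <- vapply(classes, function(cl) rowSums(m == cl, na.rm = TRUE),
                   numeric(npix))
  counts <- matrix(counts, nrow = npix)
  best <- max.col(counts, ties.method = "first")
  best_count <- counts[cbind(seq_len(npix), best)]
  # a class exceeding n/2 is necessarily the unique mode
  stable <- ifelse(best_count * 2 > d[3], classes[best], NA_integer_)
  matrix(as.integer(stable), nrow = d[1])
}

#' Build the suitable-habitat mask
#'
#' A cell is habitat when its stable land-cover class belongs to the
#' suitable set and the cell lies inside the species range.
#'
#' @param stable Stable land-cover matrix from [stable_landcover()].
#' @param suitable Integer vector of suitable class codes.
#' @param range_mask Logical matrix, `TRUE` inside the species range. Default
#'   treats the whole grid as in range.
#' @param cell_area_km2 Area of one cell in square kilometres.
#' @param codebook Optional codebook; when supplied, every suitable class
#'   must appear in it.
#' @return Logical matrix of class `habitat_mask` with attribute
#'   `cell_area_km2`.
#' @export
habitat_mask <- function(stable, suitable, range_mask = NULL,
                         cell_area_km2 = 1, codebook = NULL) {
  stopifnot(is.matrix(stable))
  if (!is.null(codebook)) {
    absent <- setdiff(suitable, as.numeric(names(codebook)))
    if (length(absent)) {
      stop("suitable classes absent from codebook: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(range_mask)) {
    range_mask <- matrix(TRUE, nrow(stable), ncol(stable))
  }
  stop_mismatch(stable, range_mask, "habitat_mask")
  m <- !is.na(stable) & matrix(stable %in% suitable, nrow(stable)) & range_mask
  structure(m, class = c("habitat_mask", "matrix", "array"),
            cell_area_km2 = cell_area_km2)
}

#' Suitable habitat area per region
#'
#' @param mask A [habitat_mask()].
#' @param regions Integer matrix of region ids (`NA` = background) on the
#'   same grid.
#' @return Data frame `(region_id, habitat_km2)` with one row per region id
#'   present in `regions`, zero where a region holds no habitat.
#' @export
habitat_area_by_region <- function(mask, regions) {
  stop_mismatch(mask, regions, "habitat_area_by_region")
  ids <- sort(unique(regions[!is.na(regions)]))
  f <- factor(regions[!is.na(regions)], levels = ids)
  cells <- tapply(as.numeric(mask[!is.na(regions)]), f, sum)
  cells[is.na(cells)] <- 0
  area <- as.numeric(cells) * (attr(mask, "cell_area_km2") %||% 1)
  data.frame(region_id = as.integer(ids), habitat_km2 = area)
}

#' Aggregate a categorical raster to a coarser grid by majority rule
#'
#' Blocks of `factor` x `factor` cells collapse to their modal class; ties
#' are broken by the smallest class code. Intended for matching a
#' fine-resolution land-cover grid to a coarser productivity grid.
#'
#' @param x Integer matrix; both dimensions must be multiples of `factor`.
#' @param factor Integer block edge length.
#' @return Integer matrix of dimension `dim(x) / factor`.
#' @export
resample_majority <- function(x, factor) {
  stopifnot(is.matrix(x), is_count(factor))
  if (nrow(x) %% factor != 0 || ncol(x) %% factor != 0) {
    stop("grid dimensions must be multiples of the aggregation factor",
         call. = FALSE)
  }
  nr <- nrow(x) %/% factor
  nc <- ncol(x) %/% factor
  out <- matrix(NA_integer_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      block <- x[((i - 1) * factor + 1):(i * factor),
                 ((j - 1) * factor + 1):(j * factor)]
      block <- block[!is.na(block)]
      if (length(block)) {
        codes <- sort(unique(block))
        tab <- tabulate(match(block, codes))
        out[i, j] <- as.integer(codes[which.max(tab)])
      }
    }
  }
  out
}
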