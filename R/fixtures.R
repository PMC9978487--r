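#' Load a packaged composite-table fixture
#'
#' The package ships transcriptions of the source study's two composite
#' tables as plain CSV: `"table1"` — regional composites (baseline + four
#' SSPs) of bacterial biomass (bulk, free-living, attached), carbon
#' demand, respiration, production, temperature, POC and DOC, with
#' spatial standard errors and cell counts; `"table2"` — the first-order
#' Taylor decomposition of changes in free-living DOC uptake rates
#' (total, DOC-control term, temperature-control term) per region and
#' SSP.
#'
#' @param name `"table1"` or `"table2"`.
#' @return An object of class `composite_fixture`: list with `name`,
#'   `values` (long `data.frame`), and for table1 a `regions`
#'   `data.frame` (cell counts `n`, ocean area percentages).
#' @examples
#' t1 <- load_fixture("table1")
#' subset(t1$values, variable == "BB" & scenario == "baseline")
#' @export
load_fixture <- function(name = c("table1", "table2")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "bactclim",
                      mustWork = TRUE)
  values <- utils::read.csv(path, stringsAsFactors = FALSE)
  regions <- c("global", "NH", "NI", "LL", "SI", "SO")
  if (name == "table1") {
    need <- expand.grid(variable = c("BB", "BB_DOC", "BB_POC", "BCD", "BR",
                                     "BP", "T", "POC", "DOC"),
                        region = regions,
                        scenario = c("baseline", "ssp126", "ssp245",
                                     "ssp370", "ssp585"))
    key <- function(d) paste(d$variable, d$region, d$scenario)
    if (!setequal(key(values), key(need)) || anyNA(values$mean))
      stop("table1 fixture fails schema check", call. = FALSE)
    meta <- utils::read.csv(system.file("extdata", "table1_regions.csv",
                                        package = "bactclim", mustWork = TRUE))
    if (!setequal(meta$region, regions))
      stop("table1 region metadata incomplete", call. = FALSE)
    out <- list(name = name, values = values, regions = meta)
  } else {
    need <- expand.grid(term = c("total", "doc_term", "temp_term"),
                        region = regions,
                        scenario = c("ssp126", "ssp245", "ssp370", "ssp585"))
    key <- function(d) paste(d$term, d$region, d$scenario)
    if (!setequal(key(values), key(need)) || anyNA(values$mean))
      stop("table2 fixture fails schema check", call. = FALSE)
    out <- list(name = name, values = values)
  }
  class(out) <- "composite_fixture"
  out
}

#' @export
print.composite_fixture <- function(x, ...) {
  cat(sprintf("composite_fixture '%s': %d rows\n", x$name, nrow(x$values)))
  invisible(x)
}

#' Taylor-decomposition residuals implied by the table-2 fixture
#'
#' For every region x SSP in the decomposition table, computes the
#' residual `total - doc_term - temp_term` and expresses it as a percent
#' of the total change — the quantity bounded at 13% in the source
#' analysis.
#'
#' @param fix A `"table2"` fixture from [load_fixture()] (loaded if
#'   missing).
#' @return `data.frame` with `region`, `scenario`, `total`, `doc_term`,
#'   `temp_term`, `residual`, `residual_pct` (absolute percent of total),
#'   and `temp_share_pct`.
#' @examples
#' max(fixture_decomposition()$residual_pct)
#' @export
fixture_decomposition <- function(fix = load_fixture("table2")) {
  stopifnot(inherits(fix, "composite_fixture"), fix$name == "table2")
  v <- fix$values
  wide <- Reduce(function(a, b) merge(a, b, by = c("region", "scenario")),
                 lapply(c("total", "doc_term", "temp_term"), function(tm) {
                   d <- v[v$term == tm, c("region", "scenario", "mean")]
                   names(d)[3] <- tm
                   d
                 }))
  wide$residual <- wide$total - wide$doc_term - wide$temp_term
  wide$residual_pct <- 100 * abs(wide$residual / wide$total)
  wide$temp_share_pct <- 100 * wide$temp_term / wide$total
  wide[order(wide$region, wide$scenario), ]
}

#' Regional baseline growth efficiencies implied by the table-1 fixture
#'
#' BGE = BP / BCD from the baseline production and carbon-demand
#' composites of each latitudinal band (and the global ocean).
#'
#' @param fix A `"table1"` fixture from [load_fixture()] (loaded if
#'   missing).
#' @return `data.frame` with `region` and `BGE`.
#' @examples
#' mean(fixture_bge()$BGE) # ~0.44
#' @export
fixture_bge <- function(fix = load_fixture("table1")) {
  stopifnot(inherits(fix, "composite_fixture"), fix$name == "table1")
  v <- fix$values[fix$values$scenario == "baseline", ]
  bp <- v[v$variable == "BP", c("region", "mean")]
  bcd <- v[v$variable == "BCD", c("region", "mean")]
  m <- merge(bp, bcd, by = "region", suffixes = c("_bp", "_bcd"))
  data.frame(region = m$region, BGE = m$mean_bp / m$mean_bcd)
}
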