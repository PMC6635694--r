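#' Measure a standardized subject: one record per bone
#'
#' Produces the linear and volumetric morphometric record of each bone
#' of a standardized set: body-frame length, width, height (bounding
#' box extents), surface area and volume, plus the three principal
#' moments of inertia. By construction the metatarsal length is 100.
#'
#' @param set a [StandardizedSet-class].
#' @param subject subject label for the records.
#' @return a data.frame with columns subject, bone, length, width,
#'   height, surface_area, volume, I1, I2, I3.
#' @export
measureSubject <- function(set, subject = "subject") {
  stopifnot(is(set, "StandardizedSet"))
  bones <- list(metatarsal = set@metatarsal,
                proximal_phalanx = set@proximal,
                distal_phalanx = set@distal)
  rows <- lapply(names(bones), function(bn) {
    m <- bones[[bn]]
    ext <- boneExtents(m)
    mp <- massProperties(m)
    pm <- principalMoments(mp)
    data.frame(subject = subject, bone = bn,
               length = ext[["length"]], width = ext[["width"]],
               height = ext[["height"]], surface_area = mp@surfaceArea,
               volume = mp@volume, I1 = pm[1], I2 = pm[2], I3 = pm[3])
  })
  do.call(rbind, rows)
}

measureNames <- c("length", "width", "height", "surface_area", "volume")
boneLevels <- c("metatarsal", "proximal_phalanx", "distal_phalanx")

#' Read / write a morphometric measurement table (CSV)
#'
#' The CSV has columns subject, bone, length, width, height,
#' surface_area, volume (one row per subject and bone). A packaged
#' example table with the first-metatarsophalangeal measurements of ten
#' athletes and the H. naledi fossil is available via
#' [mtpjMeasurements()].
#'
#' @param path CSV file.
#' @param records data.frame as produced by [measureSubject()].
#' @return `readMeasurementTable`: a data.frame.
#' @export
readMeasurementTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("subject", "bone", measureNames)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("measurement table lacks columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname readMeasurementTable
#' @export
writeMeasurementTable <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Packaged example measurement table (ten athletes and H. naledi)
#'
#' Linear and volumetric measurements of the first metatarsal,
#' proximal phalanx and distal phalanx for ten professional athletes
#' and the H. naledi fossil, with every subject's bones standardized so
#' the first metatarsal length is 100. Used as the worked example for
#' donor ranking.
#'
#' @return a data.frame in the [readMeasurementTable()] layout.
#' @export
mtpjMeasurements <- function() {
  readMeasurementTable(system.file("extdata", "mtpj_table1.csv",
                                   package = "BoneFrame", mustWork = TRUE))
}

#' Normalize a measurement table against a reference subject
#'
#' Divides every measurement value by the matching value of the
#' reference subject, giving the dimensionless ratio table used to rank
#' donor candidates. Ratios are kept at full precision; use
#' [ratioMatrix()] with `digits = 4` for the conventional 4-decimal
#' display (round half up).
#'
#' @param records measurement data.frame (subject, bone, and the five
#'   measures).
#' @param reference reference subject label.
#' @return a [RatioTable-class].
#' @examples
#' rt <- ratioTable(mtpjMeasurements(), reference = "H. naledi")
#' selectDonor(rt)
#' @export
ratioTable <- function(records, reference) {
  if (!reference %in% records$subject)
    stop("reference subject '", reference, "' not in table")
  long <- do.call(rbind, lapply(measureNames, function(m)
    data.frame(subject = records$subject, bone = records$bone,
               measure = m, value = records[[m]])))
  # completeness: every subject needs every (bone, measure) of the reference
  refrows <- long[long$subject == reference, ]
  gaps <- character()
  for (s in unique(long$subject)) {
    srows <- long[long$subject == s, ]
    key <- function(d) paste(d$bone, d$measure)
    missing <- setdiff(key(refrows), key(srows))
    if (length(missing))
      gaps <- c(gaps, paste0(s, ": ", paste(missing, collapse = ", ")))
  }
  if (length(gaps))
    stop("incomplete measurement table:\n", paste(gaps, collapse = "\n"))
  refval <- refrows$value[match(paste(long$bone, long$measure),
                                paste(refrows$bone, refrows$measure))]
  if (any(refval <= 0)) stop("reference values must be positive")
  long$ratio <- long$value / refval
  new("RatioTable", reference = reference, data = long,
      measures = measureNames)
}

#' Wide ratio matrix of a RatioTable
#'
#' @param table a [RatioTable-class].
#' @param digits when non-NULL, round half-up for display (the tables
#'   are conventionally printed at 4 decimals).
#' @return numeric matrix, one row per subject, 15 columns
#'   (bone x measure, metatarsal first).
#' @export
ratioMatrix <- function(table, digits = NULL) {
  d <- table@data
  subj <- unique(d$subject)
  cols <- as.vector(t(outer(boneLevels, table@measures, paste, sep = ".")))
  M <- matrix(NA_real_, length(subj), length(cols),
              dimnames = list(subj, cols))
  for (i in seq_along(subj)) {
    rows <- d[d$subject == subj[i], ]
    M[i, paste(rows$bone, rows$measure, sep = ".")] <- rows$ratio
  }
  if (!is.null(digits)) M <- roundHalfUp(M, digits)
  M
}

#' Score a donor candidate against the reference
#'
#' `mean_ratio` (the default) is the arithmetic mean of the subject's
#' 15 ratios; the donor search picks its minimum, i.e. the subject
#' whose measurements exceed the reference's the least on average.
#' `mean_abs_dev` is the mean of |ratio - 1|, an alternative reading of
#' "closest to the reference".
#'
#' @param table a [RatioTable-class].
#' @param subject subject label.
#' @param method "mean_ratio" or "mean_abs_dev".
#' @return the dimensionless score.
#' @export
donorScore <- function(table, subject,
                       method = c("mean_ratio", "mean_abs_dev")) {
  method <- match.arg(method)
  d <- table@data
  if (!subject %in% d$subject) stop("unknown subject '", subject, "'")
  r <- d$ratio[d$subject == subject]
  switch(method,
         mean_ratio = mean(r),
         mean_abs_dev = mean(abs(r - 1)))
}

#' Select the donor subject with the smallest score
#'
#' Returns the non-reference subject minimizing [donorScore()]. Ties
#' are broken by input order with a warning.
#'
#' @inheritParams donorScore
#' @return the donor subject's label.
#' @export
selectDonor <- function(table, method = c("mean_ratio", "mean_abs_dev")) {
  method <- match.arg(method)
  subj <- setdiff(unique(table@data$subject), table@reference)
  if (!length(subj)) stop("no non-reference subjects in table")
  sc <- vapply(subj, function(s) donorScore(table, s, method), numeric(1))
  best <- which(sc <= min(sc) + 1e-15)
  if (length(best) > 1)
    warning("tie between ", paste(subj[best], collapse = ", "),
            "; keeping the first in input order")
  subj[best[1]]
}
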