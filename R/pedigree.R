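#' Classify a gestational age into a pregnancy-loss epoch
#'
#' Losses are stratified into three developmental epochs by gestational age:
#' embryonic loss below 10 weeks, fetal death from 10 to just under 20
#' weeks, and stillbirth at 20 weeks or later. The 20-week boundary belongs
#' to stillbirth and the 10-week boundary to fetal death, so the three
#' intervals partition all gestational ages: `[0, 10)`, `[10, 20)`,
#' `[20, Inf)` weeks, evaluated in total days (`7 * weeks + days`).
#'
#' @param weeks Integer vector of completed gestational weeks (>= 0).
#' @param days Integer vector of additional days (0-6), recycled.
#' @return Character vector: `"embryonic_loss"`, `"fetal_death"`, or
#'   `"stillbirth"`.
#' @export
#' @examples
#' classify_epoch(6, 6)   # embryonic_loss
#' classify_epoch(15, 6)  # fetal_death
#' classify_epoch(20, 0)  # stillbirth
classify_epoch <- function(weeks, days) {
  if (length(days) == 1L) days <- rep(days, length(weeks))
  if (length(weeks) != length(days))
    stop("weeks and days must have equal length")
  if (anyNA(weeks) || anyNA(days))
    stop("gestational age must be present to classify an epoch")
  if (any(weeks < 0)) stop("gestational weeks must be >= 0")
  if (any(days < 0 | days > 6)) stop("gestational days must be in 0-6")
  total <- 7L * as.integer(weeks) + as.integer(days)
  ifelse(total < 70L, "embryonic_loss",
         ifelse(total < 140L, "fetal_death", "stillbirth"))
}

.sex_levels     <- c("male", "female", "unknown")
.outcome_levels <- c("parent", "live_birth", "loss")
.epoch_levels   <- c("embryonic_loss", "fetal_death", "stillbirth",
                     "live_birth", "not_applicable")
.loss_epochs    <- c("embryonic_loss", "fetal_death", "stillbirth")

# parse "<W>w<D>d" gestational-age strings; "." / "" / NA -> NA weeks/days
parse_ga <- function(x) {
  out <- data.table(ga_weeks = rep(NA_integer_, length(x)),
                    ga_days  = rep(NA_integer_, length(x)))
  present <- !is.na(x) & x != "." & x != ""
  if (any(present)) {
    m <- regmatches(x[present], regexec("^([0-9]+)w([0-9])d$", x[present]))
    bad <- vapply(m, length, 1L) != 3L
    if (any(bad))
      stop("malformed gestational age (expected '<W>w<D>d'): ",
           paste(x[present][bad], collapse = ", "))
    wk <- as.integer(vapply(m, `[`, "", 2L))
    dy <- as.integer(vapply(m, `[`, "", 3L))
    if (any(dy > 6L))
      stop("gestational days must be in 0-6: ",
           paste(x[present][dy > 6L], collapse = ", "))
    out$ga_weeks[present] <- wk
    out$ga_days[present]  <- dy
  }
  out
}

format_ga <- function(weeks, days) {
  ifelse(is.na(weeks), ".", sprintf("%dw%dd", weeks, days))
}

normalize_sex <- function(x) {
  x <- tolower(as.character(x))
  out <- rep(NA_character_, length(x))
  out[x %in% c("1", "m", "male")]   <- "male"
  out[x %in% c("2", "f", "female")] <- "female"
  out[x %in% c("0", ".", "u", "unknown", "na")] <- "unknown"
  if (anyNA(out))
    stop("unrecognized sex code(s): ", paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Read an extended pedigree file
#'
#' The file is whitespace-delimited with no header, one individual per row,
#' using the six standard PED columns (family, individual, father, mother,
#' sex, phenotype) followed by two extension columns: pregnancy `outcome`
#' (`parent`, `live_birth`, or `loss`) and gestational age as `<W>w<D>d`
#' (or `.` when not applicable). An optional ninth column `sampled` (1/0)
#' marks whether a WGS sample exists for the individual (default 1), so
#' conceptuses without DNA can still be recorded. `0` or `.` denotes a
#' missing parent. Lines starting with `#` are ignored.
#'
#' Validation enforces: referenced parents exist in the same family with the
#' expected sex; every loss has a gestational age (its epoch cannot be
#' assigned otherwise and the file is rejected); parents get epoch
#' `not_applicable` and live births epoch `live_birth`.
#'
#' @param path Path to the pedigree file.
#' @return A `data.table` with columns `individual_id`, `family_id`,
#'   `father_id`, `mother_id` (NA when missing), `sex`, `outcome`,
#'   `ga_weeks`, `ga_days`, `epoch`, `has_sample`.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines_kept <- lines[keep]
  lineno <- which(keep)
  if (length(lines_kept) == 0L) stop("pedigree file is empty: ", path)
  fields <- strsplit(trimws(lines_kept), "\\s+")
  nf <- vapply(fields, length, 1L)
  bad <- nf < 8L | nf > 9L
  if (any(bad))
    stop("malformed pedigree line ", lineno[which(bad)[1L]],
         ": expected 8 or 9 whitespace-delimited fields, got ", nf[which(bad)[1L]])
  fld <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else "1", "")
  ped <- data.table(
    family_id     = fld(1L),
    individual_id = fld(2L),
    father_id     = fld(3L),
    mother_id     = fld(4L),
    sex           = normalize_sex(fld(5L)),
    outcome       = fld(7L),
    ga_raw        = fld(8L),
    sampled_raw   = fld(9L),
    line          = lineno
  )
  ped[father_id %in% c("0", "."), father_id := NA_character_]
  ped[mother_id %in% c("0", "."), mother_id := NA_character_]
  bad_out <- !ped$outcome %in% .outcome_levels
  if (any(bad_out))
    stop("pedigree line ", ped$line[bad_out][1L], ": unknown outcome '",
         ped$outcome[bad_out][1L], "' (expected parent/live_birth/loss)")
  if (anyDuplicated(ped$individual_id))
    stop("duplicated individual_id in pedigree: ",
         ped$individual_id[duplicated(ped$individual_id)][1L])
  ga <- parse_ga(ped$ga_raw)
  ped[, `:=`(ga_weeks = ga$ga_weeks, ga_days = ga$ga_days)]
  ped[, has_sample := !sampled_raw %in% c("0")]
  ped[, c("ga_raw", "sampled_raw") := NULL]

  # referential integrity: parents exist, same family, expected sex
  for (side in c("father", "mother")) {
    col <- paste0(side, "_id")
    want_sex <- if (side == "father") "male" else "female"
    refs <- ped[!is.na(get(col))]
    miss <- !refs[[col]] %in% ped$individual_id
    if (any(miss))
      stop("pedigree line ", refs$line[miss][1L], ": ", side, "_id '",
           refs[[col]][miss][1L], "' not present in the file")
    par <- ped[match(refs[[col]], individual_id)]
    off_fam <- refs$family_id != par$family_id
    if (any(off_fam))
      stop("pedigree line ", refs$line[off_fam][1L], ": ", side, "_id '",
           refs[[col]][off_fam][1L], "' belongs to a different family")
    bad_sex <- par$sex != want_sex
    if (any(bad_sex))
      stop("pedigree line ", refs$line[bad_sex][1L], ": ", side, "_id '",
           refs[[col]][bad_sex][1L], "' does not have sex ", want_sex)
  }

  no_ga <- ped$outcome == "loss" & is.na(ped$ga_weeks)
  if (any(no_ga))
    stop("pedigree line ", ped$line[no_ga][1L], ": individual '",
         ped$individual_id[no_ga][1L],
         "' is a loss without gestational age; epoch cannot be assigned")

  ped[, epoch := "not_applicable"]
  ped[outcome == "live_birth", epoch := "live_birth"]
  ped[outcome == "loss", epoch := classify_epoch(ga_weeks, ga_days)]
  ped[, line := NULL]
  setcolorder(ped, c("individual_id", "family_id", "father_id", "mother_id",
                     "sex", "outcome", "ga_weeks", "ga_days", "epoch",
                     "has_sample"))
  ped[]
}

#' Write an extended pedigree file
#'
#' Inverse of [read_pedigree()]: emits the 6+2(+1) column dialect so that
#' reading the file back reproduces the table.
#'
#' @param ped Pedigree `data.table` as returned by [read_pedigree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  ped <- as.data.table(ped)
  out <- data.table(
    ped$family_id, ped$individual_id,
    ifelse(is.na(ped$father_id), "0", ped$father_id),
    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    c(male = "1", female = "2", unknown = "0")[ped$sex],
    "0",
    ped$outcome,
    format_ga(ped$ga_weeks, ped$ga_days),
    ifelse(ped$has_sample, "1", "0")
  )
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Human-readable description of a pedigree individual
#'
#' E.g. `"Male fetal death (15 weeks 6 days)"` or `"Female live birth"`.
#'
#' @param ped Pedigree table.
#' @param ids Individual ids to describe.
#' @return Character vector, one description per id.
#' @export
describe_individual <- function(ped, ids) {
  ped <- as.data.table(ped)
  rows <- ped[match(ids, individual_id)]
  sex_lab <- c(male = "Male", female = "Female", unknown = "Unknown sex")[rows$sex]
  what <- fcase(
    rows$outcome == "parent", "parent",
    rows$outcome == "live_birth", "live birth",
    rows$epoch == "embryonic_loss", "embryonic loss",
    rows$epoch == "fetal_death", "fetal death",
    rows$epoch == "stillbirth", "stillbirth"
  )
  ga <- ifelse(is.na(rows$ga_weeks), "",
               ifelse(rows$ga_days == 0L,
                      sprintf(" (%d weeks)", rows$ga_weeks),
                      sprintf(" (%d weeks %d days)", rows$ga_weeks, rows$ga_days)))
  paste0(sex_lab, " ", what, ga)
}
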