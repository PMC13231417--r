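#' Default body weights by species
#'
#' Typical body weights used throughout interspecies scaling: 0.025 kg
#' (mouse), 0.25 kg (rat), 2.5 kg (cynomolgus monkey, "nhp") and 70 kg
#' (human).
#'
#' @return Named numeric vector of body weights in kg.
#' @export
#' @examples
#' species_weights()["nhp"]
species_weights <- function() {
  c(mouse = 0.025, rat = 0.25, nhp = 2.5, human = 70)
}

#' Construct a concentration-time PK dataset
#'
#' Bundles observation records and dosing events for one or more subjects
#' into a validated long-format dataset, the common currency of the NCA,
#' estimation and synthetic-study functions.
#'
#' @param records data.frame with columns `subject_id`, `species`,
#'   `weight` (kg), `time` (h since first dose), `conc` (ug/mL), `blq`
#'   (logical below-limit-of-quantification flag) and optionally `lloq`
#'   (ug/mL, `NA` when unknown).
#' @param doses data.frame with columns `subject_id`, `time` (h), `amount`
#'   (ug of mRNA-LNP) and `duration` (h of zero-order infusion; 0 = bolus).
#' @param metadata Free-form list (study label, compound label, ...).
#'
#' @details Validation enforces: positive weights and dose amounts,
#'   non-negative times and durations, records sorted by time within
#'   subject with no duplicated (subject, time) pairs, strictly increasing
#'   dose times per subject, and at least one dose at or before every
#'   observation. Concentrations must be non-negative when `blq` is
#'   `FALSE`; the concentration field of BLQ rows is ignored.
#'
#' @return An object of class `pk_dataset`.
#' @export
pk_dataset <- function(records, doses, metadata = list()) {
  rec_cols <- c("subject_id", "species", "weight", "time", "conc", "blq")
  dose_cols <- c("subject_id", "time", "amount", "duration")
  for (col in rec_cols) {
    if (!col %in% names(records)) {
      stop("records is missing mandatory column '", col, "'", call. = FALSE)
    }
  }
  if (!"lloq" %in% names(records)) {
    records[["lloq"]] <- rep(NA_real_, nrow(records))
  }
  for (col in dose_cols) {
    if (!col %in% names(doses)) {
      stop("doses is missing mandatory column '", col, "'", call. = FALSE)
    }
  }
  records <- records[, c(rec_cols, "lloq")]
  doses <- doses[, dose_cols]
  records$subject_id <- as.character(records$subject_id)
  records$species <- as.character(records$species)
  records$blq <- as.logical(records$blq)
  doses$subject_id <- as.character(doses$subject_id)
  rownames(records) <- NULL
  rownames(doses) <- NULL
  ds <- structure(list(records = records, doses = doses, metadata = metadata),
                  class = "pk_dataset")
  validate_pk_dataset(ds)
  ds
}

#' Validate a pk_dataset
#'
#' @param ds A `pk_dataset`.
#' @return `ds`, invisibly, if all invariants hold; otherwise an error.
#' @export
validate_pk_dataset <- function(ds) {
  rec <- ds$records
  dos <- ds$doses
  bad <- which(!is.finite(rec$weight) | rec$weight <= 0)
  if (length(bad)) {
    stop("non-positive body weight in records at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(rec$time) | rec$time < 0)
  if (length(bad)) {
    stop("negative observation time at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!rec$blq & (!is.finite(rec$conc) | rec$conc < 0))
  if (length(bad)) {
    stop("negative or missing concentration in non-BLQ records at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(dos$amount) | dos$amount <= 0)
  if (length(bad)) {
    stop("dose amount must be > 0 at dose row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(dos$duration) | dos$duration < 0 |
                 !is.finite(dos$time) | dos$time < 0)
  if (length(bad)) {
    stop("negative dose time or duration at dose row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (id in unique(rec$subject_id)) {
    rt <- rec$time[rec$subject_id == id]
    if (is.unsorted(rt)) {
      stop("records for subject '", id, "' are not sorted by time",
           call. = FALSE)
    }
    if (anyDuplicated(rt)) {
      stop("duplicate observation times for subject '", id, "'",
           call. = FALSE)
    }
    dt <- dos$time[dos$subject_id == id]
    if (!length(dt)) {
      stop("subject '", id, "' has observations but no dose events",
           call. = FALSE)
    }
    if (any(diff(dt) <= 0)) {
      stop("dose times for subject '", id,
           "' are not strictly increasing", call. = FALSE)
    }
    if (min(rt) < min(dt)) {
      stop("subject '", id, "' has an observation before any dose",
           call. = FALSE)
    }
  }
  invisible(ds)
}

#' @export
print.pk_dataset <- function(x, ...) {
  rec <- x$records
  cat("PK dataset:", length(unique(rec$subject_id)), "subjects,",
      nrow(rec), "observations,", nrow(x$doses), "dose events\n")
  tab <- table(rec$species)
  cat("Species:", paste(sprintf("%s (%d obs)", names(tab), tab),
                        collapse = ", "), "\n")
  if (any(rec$blq)) cat("BLQ observations:", sum(rec$blq), "\n")
  invisible(x)
}

# NONMEM-flavoured column dialect used on disk
.pk_default_schema <- function() {
  list(id = "ID", time = "TIME", dv = "DV", amt = "AMT", dur = "DUR",
       evid = "EVID", mdv = "MDV", wt = "WT", species = "SPECIES",
       blq = "BLQ", lloq = "LLOQ")
}

.num17 <- function(x) {
  out <- ifelse(is.na(x), ".", formatC(x, digits = 17, format = "g"))
  out
}

.parse_num <- function(x) {
  x[x == "."] <- NA
  as.numeric(x)
}

#' Read a PK dataset from a NONMEM-style CSV file
#'
#' The on-disk dialect has one row per event: dose rows carry `EVID = 1`
#' with `AMT` (ug) and `DUR` (h); observation rows carry `EVID = 0` with
#' `DV` (ug/mL), `BLQ` (0/1) and optional `LLOQ`. `WT` (kg) and `SPECIES`
#' annotate every row; missing numeric values are written as `.`.
#'
#' @param path Path to a CSV file.
#' @param schema Named list mapping canonical column roles (`id`, `time`,
#'   `dv`, `amt`, `dur`, `evid`, `mdv`, `wt`, `species`, `blq`, `lloq`)
#'   to the actual column names in the file; unspecified roles use the
#'   defaults (`ID`, `TIME`, `DV`, ...).
#' @return A `pk_dataset`.
#' @export
read_pk_dataset <- function(path, schema = list()) {
  sch <- utils::modifyList(.pk_default_schema(), schema)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  mandatory <- c("id", "time", "evid")
  for (role in names(sch)) {
    if (!sch[[role]] %in% names(raw)) {
      if (role %in% mandatory) {
        stop("input file is missing mandatory column '", sch[[role]], "'",
             call. = FALSE)
      }
      raw[[sch[[role]]]] <- "."
    }
  }
  evid <- .parse_num(raw[[sch$evid]])
  is_dose <- !is.na(evid) & evid == 1
  is_obs <- !is.na(evid) & evid == 0
  blq_raw <- .parse_num(raw[[sch$blq]])
  records <- data.frame(
    subject_id = raw[[sch$id]][is_obs],
    species = ifelse(raw[[sch$species]][is_obs] == ".", NA,
                     raw[[sch$species]][is_obs]),
    weight = .parse_num(raw[[sch$wt]][is_obs]),
    time = .parse_num(raw[[sch$time]][is_obs]),
    conc = .parse_num(raw[[sch$dv]][is_obs]),
    blq = !is.na(blq_raw[is_obs]) & blq_raw[is_obs] == 1,
    lloq = .parse_num(raw[[sch$lloq]][is_obs]),
    stringsAsFactors = FALSE
  )
  doses <- data.frame(
    subject_id = raw[[sch$id]][is_dose],
    time = .parse_num(raw[[sch$time]][is_dose]),
    amount = .parse_num(raw[[sch$amt]][is_dose]),
    duration = .parse_num(raw[[sch$dur]][is_dose]),
    stringsAsFactors = FALSE
  )
  doses$duration[is.na(doses$duration)] <- 0
  pk_dataset(records, doses)
}

#' Write a PK dataset to a NONMEM-style CSV file
#'
#' Inverse of [read_pk_dataset()]: `read_pk_dataset(write_pk_dataset(ds, f))`
#' reproduces `ds` exactly (strings and flags identically, numerics to
#' better than 1e-12 relative).
#'
#' @param ds A `pk_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(ds, path) {
  rec <- ds$records
  dos <- ds$doses
  # species / weight per subject, taken from the observation records
  subj <- unique(rec[, c("subject_id", "species", "weight")])
  d_species <- subj$species[match(dos$subject_id, subj$subject_id)]
  d_weight <- subj$weight[match(dos$subject_id, subj$subject_id)]
  nd <- nrow(dos)
  no <- nrow(rec)
  dose_rows <- data.frame(
    ID = dos$subject_id, TIME = .num17(dos$time), DV = rep(".", nd),
    AMT = .num17(dos$amount), DUR = .num17(dos$duration),
    EVID = rep("1", nd), MDV = rep("1", nd), WT = .num17(d_weight),
    SPECIES = ifelse(is.na(d_species), ".", d_species),
    BLQ = rep("0", nd), LLOQ = rep(".", nd), stringsAsFactors = FALSE
  )
  obs_rows <- data.frame(
    ID = rec$subject_id, TIME = .num17(rec$time),
    DV = .num17(rec$conc), AMT = rep(".", no), DUR = rep(".", no),
    EVID = rep("0", no), MDV = rep("0", no), WT = .num17(rec$weight),
    SPECIES = ifelse(is.na(rec$species), ".", rec$species),
    BLQ = ifelse(rec$blq, "1", "0"), LLOQ = .num17(rec$lloq),
    stringsAsFactors = FALSE
  )
  all_rows <- rbind(dose_rows, obs_rows)
  # keep subjects in their order of appearance so read inverts write
  subj_order <- unique(c(dos$subject_id, rec$subject_id))
  ord <- order(match(all_rows$ID, subj_order),
               as.numeric(all_rows$TIME), -as.numeric(all_rows$EVID))
  utils::write.csv(all_rows[ord, ], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
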