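# Data model and file I/O for two-channel endpoint-fluorescence plates.
#
# One well = one KASP reaction read at endpoint on two fluorescence
# channels: the FAM-reported mutant/variant allele (rfu_mut) and the
# HEX-reported wildtype allele (rfu_wt). The channel-to-allele mapping is
# a fixed convention of this package and is recorded in the panel.

#' Well roles recognised on a genotyping plate
#'
#' `clone` wells carry the samples being genotyped (single-cell or
#' multi-cell clones); the three `control_*` roles are the genotype anchor
#' controls; `ntc` is the no-template control defining the no-amplification
#' baseline; `input_dna`, `ip` and `igg` are the ChIPnQASO roles (sheared
#' input chromatin, antibody pulldown, and the nonspecific-antibody
#' control).
#'
#' @format character vector of the eight role labels.
#' @export
PLATE_ROLES <- c("clone", "control_wt_wt", "control_wt_mut",
                 "control_mut_mut", "ntc", "input_dna", "ip", "igg")

PLATE_COLUMNS <- c("plate_id", "well", "sample_id", "role", "antibody",
                   "rfu_mut", "rfu_wt")

# Valid well ids for the 384-well grid (A-P x 1-24); 96-well plates
# (A-H x 1-12) are a subset of the same grammar.
valid_well <- function(well) {
  grepl("^[A-P]([1-9]|1[0-9]|2[0-4])$", well)
}

#' Construct a plate panel
#'
#' A panel holds all wells of one KASP assay run on one plate: the assay
#' identity (variant name plus its two allele labels) and a table of well
#' readings.
#'
#' @param readings tibble/data.frame with columns `plate_id`, `well`,
#'   `sample_id`, `role`, `antibody` (may be `NA` except for `ip` wells),
#'   `rfu_mut`, `rfu_wt`.
#' @param assay_id assay label, e.g. the variant name (`"rs6983267"`).
#' @param allele_mut,allele_wt labels of the mutant (FAM) and wildtype
#'   (HEX) alleles.
#' @return object of class `plate_panel`.
#' @examples
#' plate_panel(
#'   tibble::tibble(
#'     plate_id = "p1", well = c("A1", "A2"), sample_id = c("ntc1", "c1"),
#'     role = c("ntc", "clone"), antibody = NA_character_,
#'     rfu_mut = c(55, 1900), rfu_wt = c(62, 140)),
#'   assay_id = "rs6983267", allele_mut = "T", allele_wt = "G")
#' @export
plate_panel <- function(readings, assay_id = "assay", allele_mut = "mut",
                        allele_wt = "wt") {
  readings <- as_tibble(readings)
  if (!"antibody" %in% names(readings)) readings$antibody <- NA_character_
  missing <- setdiff(PLATE_COLUMNS, names(readings))
  if (length(missing) > 0) {
    stop_format(paste0("missing required column(s): ",
                       paste(missing, collapse = ", ")))
  }
  readings <- readings[PLATE_COLUMNS]
  readings$antibody[!is.na(readings$antibody) &
                      readings$antibody == ""] <- NA_character_
  validate_readings(readings)
  structure(
    list(assay_id = assay_id, allele_mut = allele_mut,
         allele_wt = allele_wt, readings = readings),
    class = "plate_panel")
}

validate_readings <- function(readings) {
  if (nrow(readings) == 0) stop_validation("panel must contain at least one reading")
  bad_well <- !valid_well(readings$well)
  if (any(bad_well)) {
    stop_validation(paste0("invalid well id(s) for a 384-well grid: ",
                           paste(unique(readings$well[bad_well]), collapse = ", ")))
  }
  bad_role <- !readings$role %in% PLATE_ROLES
  if (any(bad_role)) {
    stop_validation(paste0("unknown role(s): ",
                           paste(unique(readings$role[bad_role]), collapse = ", "),
                           " (well ",
                           paste(readings$well[bad_role], collapse = ", "), ")"))
  }
  for (ch in c("rfu_mut", "rfu_wt")) {
    v <- readings[[ch]]
    if (!is.numeric(v) || anyNA(v)) {
      stop_validation(paste0("non-numeric or missing ", ch, " (well ",
                             paste(readings$well[!is.finite(v)], collapse = ", "), ")"))
    }
    if (any(v < 0)) {
      stop_validation(paste0("negative ", ch, " (well ",
                             paste(readings$well[v < 0], collapse = ", "), ")"))
    }
  }
  dup <- duplicated(paste(readings$plate_id, readings$well))
  if (any(dup)) {
    stop_validation(paste0("duplicate well(s): ",
                           paste(unique(readings$well[dup]), collapse = ", ")))
  }
  key <- paste(readings$sample_id, readings$well)
  if (anyDuplicated(key)) {
    stop_validation("sample_id + well must be unique within a panel")
  }
  need_ab <- readings$role == "ip" & is.na(readings$antibody)
  if (any(need_ab)) {
    stop_validation(paste0("ip wells require an antibody (well ",
                           paste(readings$well[need_ab], collapse = ", "), ")"))
  }
  invisible(readings)
}

#' @export
print.plate_panel <- function(x, ...) {
  cat("<plate_panel> assay", x$assay_id,
      sprintf("[mut=%s (FAM), wt=%s (HEX)]", x$allele_mut, x$allele_wt),
      "-", nrow(x$readings), "wells\n")
  tab <- table(x$readings$role)
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a plate CSV
#'
#' Parses the canonical plate dialect: UTF-8, comma-separated, header
#' `plate_id,well,sample_id,role,antibody,rfu_mut,rfu_wt`, decimal point
#' regardless of locale, empty `antibody` allowed. Rejections name the
#' offending column or well.
#'
#' @param path file to read.
#' @param assay_id,allele_mut,allele_wt panel metadata (not stored in the
#'   file; instrument exports carry them out of band).
#' @return a [plate_panel()].
#' @seealso [write_plate_csv()]
#' @export
read_plate_csv <- function(path, assay_id = "assay", allele_mut = "mut",
                           allele_wt = "wt") {
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8")
  missing <- setdiff(PLATE_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stop_format(paste0("missing required column(s): ",
                       paste(missing, collapse = ", ")))
  }
  raw <- as_tibble(raw[PLATE_COLUMNS])
  for (ch in c("rfu_mut", "rfu_wt")) {
    v <- suppressWarnings(as.numeric(raw[[ch]]))
    bad <- is.na(v) & !is.na(raw[[ch]])
    if (any(bad) || anyNA(raw[[ch]])) {
      stop_format(paste0("column ", ch, " is not numeric (well ",
                         paste(raw$well[bad | is.na(raw[[ch]])], collapse = ", "),
                         ")"))
    }
    raw[[ch]] <- v
  }
  raw$antibody[raw$antibody == ""] <- NA_character_
  plate_panel(raw, assay_id = assay_id, allele_mut = allele_mut,
              allele_wt = allele_wt)
}

#' Write a plate CSV
#'
#' Emits the canonical dialect read by [read_plate_csv()]; RFUs are written
#' with 9 significant digits so that write-then-read reproduces a panel
#' exactly and a second write is byte-identical.
#'
#' @param panel a [plate_panel()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(panel, path) {
  stopifnot(inherits(panel, "plate_panel"))
  validate_readings(panel$readings)
  r <- panel$readings
  lines <- c(
    paste(PLATE_COLUMNS, collapse = ","),
    paste(r$plate_id, r$well, r$sample_id, r$role,
          ifelse(is.na(r$antibody), "", r$antibody),
          format_rfu(r$rfu_mut), format_rfu(r$rfu_wt), sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Check a panel against minimum role counts
#'
#' A screening plate is interpretable only if its anchors are present:
#' genotype controls for each class and no-template controls. The default
#' requirement (2 of each control class, 2 NTCs) reflects the smallest
#' layout that allows a dispersion estimate per anchor.
#'
#' @param panel a [plate_panel()].
#' @param requirements named integer vector/list of minimum counts per role.
#' @return list with `ok` (logical) and `deficits`, a tibble with one row
#'   per role below requirement (`role`, `have`, `need`).
#' @examples
#' p <- plate_panel(tibble::tibble(
#'   plate_id = "p", well = "A1", sample_id = "s", role = "clone",
#'   antibody = NA, rfu_mut = 1, rfu_wt = 1))
#' validate_layout(p)$ok
#' @export
validate_layout <- function(panel,
                            requirements = c(control_wt_wt = 2,
                                             control_wt_mut = 2,
                                             control_mut_mut = 2,
                                             ntc = 2)) {
  stopifnot(inherits(panel, "plate_panel"))
  requirements <- unlist(requirements)
  bad <- setdiff(names(requirements), PLATE_ROLES)
  if (length(bad) > 0) {
    stop_validation(paste0("unknown role(s) in requirements: ",
                           paste(bad, collapse = ", ")))
  }
  have <- table(factor(panel$readings$role, levels = PLATE_ROLES))
  deficits <- tibble(
    role = names(requirements),
    have = as.integer(have[names(requirements)]),
    need = as.integer(requirements))
  deficits <- deficits[deficits$have < deficits$need, ]
  list(ok = nrow(deficits) == 0, deficits = deficits)
}
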