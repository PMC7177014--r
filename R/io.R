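# Standard-format I/O: fixed-column GRO coordinates, XYZ dumps, TSV tables
# with '#'-prefixed headers, YAML run configuration with strict validation.

atom_names_for <- function(sys) {
  nm <- character(nrow(sys$pos))
  for (lip in unique(sys$lipid_id[sys$lipid_id > 0])) {
    idx <- which(sys$lipid_id == lip)
    nm[idx] <- c("H", paste0("T", seq_len(length(idx) - 1L)))
  }
  if (length(sys$probe_idx)) {
    nm[sys$probe_idx] <- paste0(ifelse(sys$att[sys$probe_idx] == 3L, "PH", "PP"),
                                seq_along(sys$probe_idx))
  }
  nm
}

#' Write a system to a GRO coordinate file
#'
#' Fixed-column GRO (nm, 3 decimals; velocities in nm/ps, 4 decimals).
#'
#' @param sys A `membrane_system`.
#' @param path Output file.
#' @param title Title line.
#' @param velocities Include velocity columns.
#' @return `path`, invisibly.
#' @export
write_gro <- function(sys, path, title = "thinmem configuration",
                      velocities = TRUE) {
  n <- nrow(sys$pos)
  res_id <- ifelse(sys$lipid_id > 0, sys$lipid_id,
                   max(sys$lipid_id) + 1L)
  res_nm <- ifelse(sys$lipid_id > 0,
                   sys$species_of_lipid[pmax(sys$lipid_id, 1L)], "PRB")
  at_nm <- atom_names_for(sys)
  lines <- character(n + 3L)
  lines[1] <- title
  lines[2] <- sprintf("%5d", n)
  for (i in seq_len(n)) {
    base <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    res_id[i] %% 100000L, substr(res_nm[i], 1, 5),
                    substr(at_nm[i], 1, 5), i %% 100000L,
                    sys$pos[i, 1], sys$pos[i, 2], sys$pos[i, 3])
    if (velocities)
      base <- paste0(base, sprintf("%8.4f%8.4f%8.4f",
                                   sys$vel[i, 1], sys$vel[i, 2], sys$vel[i, 3]))
    lines[i + 2L] <- base
  }
  lines[n + 3L] <- sprintf("%10.5f%10.5f%10.5f", sys$box[1], sys$box[2], sys$box[3])
  writeLines(lines, path)
  invisible(path)
}

#' Read a GRO coordinate file
#'
#' @param path GRO file.
#' @return List with `pos` (N x 3), `vel` (N x 3 or NULL), `res_id`,
#'   `res_name`, `atom_name`, `box`, `title`.
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  body <- lines[3:(n + 2L)]
  num <- function(s) as.numeric(s)
  pos <- matrix(0, n, 3); vel <- matrix(NA_real_, n, 3)
  res_id <- integer(n); res_name <- character(n); atom_name <- character(n)
  for (i in seq_len(n)) {
    ln <- body[i]
    res_id[i] <- as.integer(substr(ln, 1, 5))
    res_name[i] <- trimws(substr(ln, 6, 10))
    atom_name[i] <- trimws(substr(ln, 11, 15))
    pos[i, ] <- c(num(substr(ln, 21, 28)), num(substr(ln, 29, 36)),
                  num(substr(ln, 37, 44)))
    if (nchar(ln) >= 68) {
      vel[i, ] <- c(num(substr(ln, 45, 52)), num(substr(ln, 53, 60)),
                    num(substr(ln, 61, 68)))
    }
  }
  box <- as.numeric(strsplit(trimws(lines[n + 3L]), "\\s+")[[1]])[1:3]
  list(pos = pos, vel = if (all(is.na(vel))) NULL else vel,
       res_id = res_id, res_name = res_name, atom_name = atom_name,
       box = box, title = lines[1])
}

#' Restart a system from GRO coordinates
#'
#' Replaces positions (and velocities, if present) of a built system with
#' those read from a GRO file written for the same topology.
#'
#' @param sys A `membrane_system` built with the same parameters.
#' @param path GRO file.
#' @return The updated system.
#' @export
restore_coordinates <- function(sys, path) {
  g <- read_gro(path)
  if (nrow(g$pos) != nrow(sys$pos))
    stop("GRO file has ", nrow(g$pos), " beads but the system has ",
         nrow(sys$pos), call. = FALSE)
  sys$pos <- g$pos
  if (!is.null(g$vel)) sys$vel <- g$vel
  sys
}

#' Write trajectory frames as a multi-frame XYZ file
#'
#' @param frames List of N x 3 matrices (nm).
#' @param path Output file.
#' @param labels Per-bead element labels; default "C".
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, labels = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    p <- frames[[f]]
    if (is.null(labels)) labels <- rep("C", nrow(p))
    writeLines(c(sprintf("%d", nrow(p)), sprintf("frame %d", f)), con)
    writeLines(sprintf("%-4s %12.6f %12.6f %12.6f",
                       labels, p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file
#' @param path XYZ file.
#' @return List of N x 3 coordinate matrices.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(trimws(lines[i]))
    block <- lines[(i + 2L):(i + 1L + n)]
    sp <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    frames[[length(frames) + 1L]] <-
      matrix(as.numeric(sp[, 2:4]), ncol = 3)
    i <- i + 2L + n
  }
  frames
}

#' Write a TSV table with a '#'-prefixed header line
#' @param df Data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TSV table written by [write_tsv()]
#' @param path File path.
#' @return Data.frame.
#' @export
read_tsv <- function(path) {
  hdr <- sub("^#\\s*", "", readLines(path, n = 1))
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  names(df) <- strsplit(hdr, "\t")[[1]]
  df
}

#' Write the per-lipid species map sidecar
#' @param sys A `membrane_system`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_species_map <- function(sys, path) {
  lip <- seq_along(sys$species_of_lipid)
  lf <- vapply(lip, function(l) sys$leaflet[match(l, sys$lipid_id)], integer(1))
  write_tsv(data.frame(lipid_id = lip, species = sys$species_of_lipid,
                       leaflet = ifelse(lf == 1L, "upper", "lower")), path)
}

# --- run configuration ------------------------------------------------------

config_schema <- list(
  geometry = c("X_box", "A_thin", "A_buffer", "box_y", "box_z"),
  thinning = c("enabled", "k", "D"),
  composition = NULL,                 # species names, validated separately
  build = c("area_per_lipid", "seed", "T"),
  run = c("dt", "T", "friction", "n_steps", "frame_stride", "log_stride",
          "seed"),
  analysis = c("n_bins_thickness", "n_bins_sorting", "grid_spacing",
               "A_min", "p_min", "n_blocks"),
  umbrella = c("x_start", "x_end", "spacing", "k_u", "equil_steps",
               "prod_steps", "seed", "n_probe_beads"),
  output = c("dir", "prefix")
)

#' Default run configuration
#' @return Nested list mirroring the YAML config layout.
#' @export
default_config <- function() {
  list(
    geometry = list(X_box = 12, A_thin = 3, A_buffer = 2.5, box_y = 6,
                    box_z = 12),
    thinning = list(enabled = TRUE, k = 20, D = 1),
    composition = list(POPC = 1.0),
    build = list(area_per_lipid = 0.475, seed = 1, T = 310),
    run = list(dt = 0.02, T = 310, friction = 1, n_steps = 20000,
               frame_stride = 500, log_stride = 100, seed = 1),
    analysis = list(n_bins_thickness = 110, n_bins_sorting = 50,
                    grid_spacing = 0.1, A_min = 15, p_min = 1e-4,
                    n_blocks = 10),
    umbrella = list(x_start = 6, x_end = 2, spacing = 0.5, k_u = 1000,
                    equil_steps = 2000, prod_steps = 10000, seed = 1,
                    n_probe_beads = 8),
    output = list(dir = "thinmem_out", prefix = "run")
  )
}

#' Validate a run configuration
#'
#' Unknown sections or keys are rejected; composition species must be
#' registered; every random procedure must have an explicit seed.
#'
#' @param cfg Nested configuration list.
#' @param species_table Registered species.
#' @return The validated config (with defaults filled in), or an error.
#' @export
validate_config <- function(cfg, species_table = default_species()) {
  if (!is.list(cfg)) stop("config must be a mapping", call. = FALSE)
  bad <- setdiff(names(cfg), names(config_schema))
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (sec in names(cfg)) {
    allowed <- config_schema[[sec]]
    if (is.null(allowed) && sec == "composition") {
      unknown <- setdiff(names(cfg[[sec]]), species_table$name)
      if (length(unknown))
        stop("composition: unregistered species: ",
             paste(unknown, collapse = ", "), call. = FALSE)
    } else {
      bad <- setdiff(names(cfg[[sec]]), allowed)
      if (length(bad))
        stop(sec, ": unknown key(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    }
  }
  base <- default_config()
  for (sec in names(cfg)) {
    if (sec == "composition") base[[sec]] <- cfg[[sec]]
    else base[[sec]] <- utils::modifyList(base[[sec]], cfg[[sec]])
  }
  zone_geometry(base$geometry$X_box, base$geometry$A_thin,
                base$geometry$A_buffer)   # geometry invariants
  base
}

#' Read and validate a YAML run configuration
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("cannot parse config ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  validate_config(cfg)
}

#' Write a configuration to YAML
#' @param cfg Configuration list.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' MD5 hash of a config file (for provenance records)
#' @param path File path.
#' @return Hash string.
#' @export
config_hash <- function(path) unname(tools::md5sum(path))
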