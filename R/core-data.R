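# Domain types and file I/O for amide-coupling reaction tables and conformers.

CARBODIIMIDES <- c(
  EDC = "CCN=C=NCCCN(C)C",
  DCC = "C1CCCCC1N=C=NC1CCCCC1",
  DIC = "CC(C)N=C=NC(C)C"
)

MOLECULE_ROLES <- c("acid", "amine", "product", "intermediate", "carbodiimide")

#' Construct a molecule
#'
#' A molecule is a canonical SMILES plus its role in an amide coupling and an
#' optional 3D conformer. The SMILES is canonicalized on construction.
#'
#' @param smiles SMILES string (any valid form; stored canonical).
#' @param role One of `"acid"`, `"amine"`, `"product"`, `"intermediate"`,
#'   `"carbodiimide"`.
#' @param conformer Optional [conformer3d] object.
#' @return An object of class `molecule`.
#' @export
molecule <- function(smiles, role, conformer = NULL) {
  role <- match.arg(role, MOLECULE_ROLES)
  obj <- list(smiles = canonicalize(smiles), role = role, conformer = conformer)
  class(obj) <- "molecule"
  obj
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule:", x$role, "> ", x$smiles,
      if (!is.null(x$conformer)) " [+conformer]", "\n", sep = "")
  invisible(x)
}

#' Construct a 3D conformer
#'
#' @param species Character vector of element symbols, one per atom.
#' @param coords Numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param energy Surrogate electronic energy (provider units), or `NA`.
#' @param net_charge Integer net charge.
#' @return An object of class `conformer3d`.
#' @export
conformer3d <- function(species, coords, energy = NA_real_, net_charge = 0L) {
  coords <- as.matrix(coords)
  if (length(species) != nrow(coords)) {
    stop("species/coordinate length mismatch: ", length(species), " vs ",
         nrow(coords))
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates in conformer")
  obj <- list(species = as.character(species), coords = coords,
              energy = energy, net_charge = as.integer(net_charge))
  class(obj) <- "conformer3d"
  obj
}

#' Construct a reaction context
#'
#' Categorical context labels are normalized (lowercased, whitespace-stripped);
#' missing numeric fields stay `NA` and are never imputed.
#'
#' @param reagents,solvents,conditions Character vectors of category labels.
#' @param temperature Temperature in Celsius or `NA`.
#' @param time Reaction time in hours or `NA`.
#' @return An object of class `reaction_context`.
#' @export
reaction_context <- function(reagents = character(0), solvents = character(0),
                             temperature = NA_real_, time = NA_real_,
                             conditions = character(0)) {
  norm <- function(x) {
    x <- tolower(trimws(as.character(x)))
    x <- x[nzchar(x)]
    x
  }
  obj <- list(reagents = norm(reagents), solvents = norm(solvents),
              temperature = as.numeric(temperature), time = as.numeric(time),
              conditions = norm(conditions))
  class(obj) <- "reaction_context"
  obj
}

context_labels <- function(ctx) {
  c(if (length(ctx$reagents)) paste0("reagent:", ctx$reagents),
    if (length(ctx$solvents)) paste0("solvent:", ctx$solvents),
    if (length(ctx$conditions)) paste0("condition:", ctx$conditions))
}

#' Construct a context vocabulary
#'
#' @param labels Character vector of unique, field-prefixed context labels
#'   (e.g. `"solvent:dmf"`), in a fixed order that defines the encoding.
#' @return An object of class `context_vocabulary` with fields `labels` and
#'   `dimension`.
#' @export
context_vocabulary <- function(labels) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("context vocabulary labels must be unique")
  obj <- list(labels = labels, dimension = length(labels))
  class(obj) <- "context_vocabulary"
  obj
}

#' Construct a reaction record
#'
#' One amide coupling: acid + amine -> product (+ H2O), mediated by a
#' carbodiimide coupling agent, with observed yield and context.
#'
#' @param reaction_id Unique identifier string.
#' @param acid,amine,product [molecule] objects (roles enforced).
#' @param coupling_agent One of `"EDC"`, `"DCC"`, `"DIC"`.
#' @param yield_percent Yield in percent, in `[0, 100]`.
#' @param context A [reaction_context].
#' @param intermediate Optional O-acylisourea [molecule].
#' @return An object of class `reaction_record`.
#' @export
reaction_record <- function(reaction_id, acid, amine, product, coupling_agent,
                            yield_percent, context = reaction_context(),
                            intermediate = NULL) {
  stopifnot(inherits(acid, "molecule"), inherits(amine, "molecule"),
            inherits(product, "molecule"), inherits(context, "reaction_context"))
  obj <- list(reaction_id = as.character(reaction_id), acid = acid, amine = amine,
              product = product, intermediate = intermediate,
              coupling_agent = as.character(coupling_agent),
              yield_percent = as.numeric(yield_percent), context = context)
  class(obj) <- "reaction_record"
  obj
}

#' Construct a reaction dataset
#'
#' @param records List of [reaction_record] objects (order preserved).
#' @param context_vocab Optional [context_vocabulary]; built from the records'
#'   observed labels if omitted.
#' @return An object of class `reaction_dataset`.
#' @export
reaction_dataset <- function(records, context_vocab = NULL) {
  ids <- vapply(records, function(r) r$reaction_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate reaction_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (is.null(context_vocab)) {
    labs <- unique(unlist(lapply(records, function(r) context_labels(r$context))))
    context_vocab <- context_vocabulary(sort(labs %||% character(0)))
  }
  obj <- list(records = records, context_vocab = context_vocab)
  class(obj) <- "reaction_dataset"
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
length.reaction_dataset <- function(x) length(x$records)

#' @export
print.reaction_dataset <- function(x, ...) {
  cat("<reaction_dataset> ", length(x$records), " records, context vocabulary of ",
      x$context_vocab$dimension, " labels\n", sep = "")
  invisible(x)
}

#' Extract the yield vector of a dataset
#' @param dataset A [reaction_dataset].
#' @return Numeric vector of yields (%), in record order.
#' @export
yields <- function(dataset) {
  vapply(dataset$records, function(r) r$yield_percent, numeric(1))
}

#' Subset a reaction dataset by record index
#' @param dataset A [reaction_dataset].
#' @param idx Integer or logical index over records.
#' @return A new [reaction_dataset] sharing the parent's context vocabulary.
#' @export
subset_dataset <- function(dataset, idx) {
  reaction_dataset(dataset$records[idx], dataset$context_vocab)
}

# --- validation --------------------------------------------------------------

#' Validate a reaction record
#'
#' Checks that the record describes a condensation `A + B = C + H2O`: the
#' product formula must equal formula(acid) + formula(amine) - H2O, the yield
#' must lie in `[0, 100]`, and the coupling agent must be one of the three
#' supported carbodiimides. Violations are returned, never raised.
#'
#' @param record A [reaction_record].
#' @return Character vector of violation messages; `character(0)` means ok.
#' @export
validate_record <- function(record) {
  violations <- character(0)
  if (!record$coupling_agent %in% names(CARBODIIMIDES)) {
    violations <- c(violations,
                    paste0("unknown coupling agent: ", record$coupling_agent))
  }
  if (is.na(record$yield_percent) || record$yield_percent < 0 ||
      record$yield_percent > 100) {
    violations <- c(violations, "yield out of range")
  }
  expected <- tryCatch(
    formula_subtract(formula_add(mol_formula(record$acid$smiles),
                                 mol_formula(record$amine$smiles)),
                     c(H = 2L, O = 1L)),
    error = function(e) NULL)
  actual <- tryCatch(mol_formula(record$product$smiles), error = function(e) NULL)
  if (is.null(expected) || is.null(actual)) {
    violations <- c(violations, "unparseable reactant or product SMILES")
  } else if (!formula_equal(expected, actual)) {
    violations <- c(violations,
                    paste0("formula mismatch: product ", formula_string(actual),
                           " != acid + amine - H2O (", formula_string(expected), ")"))
  }
  violations
}

# --- CSV I/O -----------------------------------------------------------------

REACTION_CSV_COLUMNS <- c(
  "reaction_id", "acid_smiles", "amine_smiles", "product_smiles",
  "intermediate_smiles", "coupling_agent", "yield", "reagents", "solvents",
  "temperature_c", "time_h", "conditions")

num_to_chr <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
chr_to_num <- function(x) ifelse(!nzchar(x), NA_real_, as.numeric(x))
join_multi <- function(x) paste(x, collapse = ";")
split_multi <- function(x) {
  if (!nzchar(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Convert a reaction dataset to a data frame
#'
#' One row per record, using the package's CSV schema (multi-valued context
#' fields `";"`-joined, missing numerics as empty strings on disk / `NA` here).
#' @param dataset A [reaction_dataset].
#' @return A `data.frame` with the columns listed in `REACTION_CSV_COLUMNS`.
#' @export
dataset_to_frame <- function(dataset) {
  rows <- lapply(dataset$records, function(r) {
    data.frame(
      reaction_id = r$reaction_id,
      acid_smiles = r$acid$smiles,
      amine_smiles = r$amine$smiles,
      product_smiles = r$product$smiles,
      intermediate_smiles = if (is.null(r$intermediate)) "" else r$intermediate$smiles,
      coupling_agent = r$coupling_agent,
      yield = r$yield_percent,
      reagents = join_multi(r$context$reagents),
      solvents = join_multi(r$context$solvents),
      temperature_c = r$context$temperature,
      time_h = r$context$time,
      conditions = join_multi(r$context$conditions),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(stringsAsFactors = FALSE))) %||%
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(REACTION_CSV_COLUMNS))),
                    REACTION_CSV_COLUMNS)
}

#' Write a reaction dataset to CSV
#'
#' Comma-separated, UTF-8, quoted fields; numerics serialized at full
#' precision so that [read_reaction_table()] round-trips every field exactly.
#'
#' @param dataset A [reaction_dataset].
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_reaction_table <- function(dataset, path) {
  df <- dataset_to_frame(dataset)
  if (nrow(df) > 0) {
    df$yield <- num_to_chr(df$yield)
    df$temperature_c <- num_to_chr(df$temperature_c)
    df$time_h <- num_to_chr(df$time_h)
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}

#' Read a reaction table from CSV
#'
#' @param path CSV file path.
#' @param schema Optional named character vector mapping the package's column
#'   names (names) to the file's column names (values), for foreign tables.
#' @return A [reaction_dataset]. Rows with invalid SMILES are collected and
#'   reported with their row indices as an error.
#' @export
read_reaction_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (ours in names(schema)) {
      theirs <- schema[[ours]]
      if (!theirs %in% names(df)) stop("schema maps missing column: ", theirs)
      names(df)[names(df) == theirs] <- ours
    }
  }
  required <- setdiff(REACTION_CSV_COLUMNS,
                      c("intermediate_smiles", "reagents", "solvents",
                        "temperature_c", "time_h", "conditions"))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("reaction table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (opt in setdiff(REACTION_CSV_COLUMNS, names(df))) df[[opt]] <- ""
  if (nrow(df) == 0) {
    return(reaction_dataset(list(), context_vocabulary(character(0))))
  }
  errors <- character(0)
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    rec <- tryCatch({
      inter <- if (nzchar(df$intermediate_smiles[i])) {
        molecule(df$intermediate_smiles[i], "intermediate")
      } else NULL
      reaction_record(
        reaction_id = df$reaction_id[i],
        acid = molecule(df$acid_smiles[i], "acid"),
        amine = molecule(df$amine_smiles[i], "amine"),
        product = molecule(df$product_smiles[i], "product"),
        intermediate = inter,
        coupling_agent = df$coupling_agent[i],
        yield_percent = chr_to_num(df$yield[i]),
        context = reaction_context(
          reagents = split_multi(df$reagents[i]),
          solvents = split_multi(df$solvents[i]),
          temperature = chr_to_num(df$temperature_c[i]),
          time = chr_to_num(df$time_h[i]),
          conditions = split_multi(df$conditions[i])))
    }, error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      errors <- c(errors, paste0("row ", i, ": ", rec))
    } else {
      records[[i]] <- rec
    }
  }
  if (length(errors) > 0) {
    stop("invalid rows in ", path, ":\n", paste(errors, collapse = "\n"))
  }
  reaction_dataset(records)
}

# --- conformer I/O -----------------------------------------------------------

#' Read a conformer from an XYZ or SDF file
#'
#' For XYZ, an `energy=<value>` token on the comment line populates the
#' energy; for SDF, a property block entry named `energy` (case-insensitive)
#' does. Missing energies are `NA`.
#'
#' @param path File path ending in `.xyz` or `.sdf`/`.mol`.
#' @return A [conformer3d].
#' @export
read_conformer <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  if (ext == "xyz") {
    n <- suppressWarnings(as.integer(trimws(lines[1])))
    if (is.na(n)) stop("malformed XYZ: first line is not an atom count")
    body <- lines[-(1:2)]
    body <- body[nzchar(trimws(body))]
    if (length(body) != n) {
      stop("malformed XYZ: declared ", n, " atoms but found ", length(body))
    }
    toks <- strsplit(trimws(body), "\\s+")
    species <- vapply(toks, `[`, character(1), 1)
    coords <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    energy <- NA_real_
    m <- regmatches(lines[2], regexpr("energy\\s*=\\s*(-?[0-9.eE+]+)", lines[2]))
    if (length(m) == 1) energy <- as.numeric(sub("energy\\s*=\\s*", "", m))
    conformer3d(species, coords, energy)
  } else if (ext %in% c("sdf", "mol")) {
    g <- parse_molblock(paste(lines, collapse = "\n"))
    energy <- NA_real_
    prop <- grep("^> *<.*energy.*>", lines, ignore.case = TRUE)
    if (length(prop) >= 1 && prop[1] < length(lines)) {
      energy <- suppressWarnings(as.numeric(trimws(lines[prop[1] + 1])))
    }
    conformer3d(g$elem, g$coords, energy, sum(g$charge))
  } else {
    stop("unsupported conformer format: .", ext)
  }
}

#' Write a conformer to an XYZ file
#'
#' @param conf A [conformer3d].
#' @param path Output path.
#' @param comment Extra text for the comment line (energy is appended
#'   automatically when present).
#' @return Invisibly, the path.
#' @export
write_conformer_xyz <- function(conf, path, comment = "") {
  hdr <- as.character(length(conf$species))
  cmt <- trimws(paste(comment,
                      if (!is.na(conf$energy)) sprintf("energy=%.10g", conf$energy)))
  body <- sprintf("%-3s %14.8f %14.8f %14.8f", conf$species,
                  conf$coords[, 1], conf$coords[, 2], conf$coords[, 3])
  writeLines(c(hdr, cmt, body), path)
  invisible(path)
}
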