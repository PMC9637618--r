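#' Variable schema for a cohort table
#'
#' A schema is a data frame with one row per variable describing its
#' measurement level and its role in the analysis. Exactly eleven variables
#' must carry the role `"network_node"`; the stratifier (`sex`) and
#' auxiliaries (`age`, `wave`) are carried alongside the node matrix.
#'
#' @param name character vector of variable names.
#' @param level one of `"continuous"`, `"ordinal"`, `"binary"` per variable.
#' @param lower,upper inclusive integer bounds for ordinal variables
#'   (`NA` for continuous/binary).
#' @param role one of `"network_node"`, `"stratifier"`, `"auxiliary"`.
#' @return a `variable_schema` data frame.
#' @export
variable_schema <- function(name, level, lower = NA_real_, upper = NA_real_,
                            role = "network_node") {
  sch <- data.frame(name = as.character(name),
                    level = as.character(level),
                    lower = as.numeric(lower),
                    upper = as.numeric(upper),
                    role = as.character(role),
                    stringsAsFactors = FALSE)
  bad <- !sch$level %in% c("continuous", "ordinal", "binary")
  if (any(bad))
    stop("unknown measurement level for: ",
         paste(sch$name[bad], collapse = ", "))
  bad <- !sch$role %in% c("network_node", "stratifier", "auxiliary")
  if (any(bad))
    stop("unknown role for: ", paste(sch$name[bad], collapse = ", "))
  if (anyDuplicated(sch$name))
    stop("duplicated variable names in schema")
  ord <- sch$level == "ordinal"
  if (any(ord & (is.na(sch$lower) | is.na(sch$upper))))
    stop("ordinal variables need lower and upper bounds")
  if (any(ord & sch$lower >= sch$upper))
    stop("ordinal bounds must satisfy lower < upper")
  class(sch) <- c("variable_schema", "data.frame")
  sch
}

#' Default 11-node schema: inflammation, depression, cognition, risk factors
#'
#' Five inflammatory biomarkers (IL-6, IL-8, IL-10, IL-12, CRP; continuous,
#' typically non-normal and zero inflated), a 0-15 geriatric depression
#' score, a global cognition z-score, education (1-5), alcohol consumption
#' frequency (1-6), a continuous cardiovascular disease risk score, and
#' APOE-e4 carrier status (binary). Sex is a hard stratifier, never a node;
#' age is auxiliary (used by attrition checks only).
#'
#' @return a `variable_schema` with 11 network nodes.
#' @export
default_schema <- function() {
  variable_schema(
    name  = c("IL6", "IL8", "IL10", "IL12", "CRP",
              "depression", "cognition", "education", "alcohol",
              "cvd_risk", "apoe4"),
    level = c(rep("continuous", 5),
              "ordinal", "continuous", "ordinal", "ordinal",
              "continuous", "binary"),
    lower = c(rep(NA, 5), 0, NA, 1, 1, NA, NA),
    upper = c(rep(NA, 5), 15, NA, 5, 6, NA, NA),
    role  = rep("network_node", 11)
  )
}

node_names <- function(schema) schema$name[schema$role == "network_node"]

#' Construct a validated cohort table
#'
#' @param values numeric matrix (subjects x network nodes), `NA` = missing.
#' @param sex character/factor with levels `male`/`female`, no missing.
#' @param age numeric vector of ages in years.
#' @param wave wave identifier, 1 or 2.
#' @param schema a [variable_schema()]; defaults to [default_schema()].
#' @param subject optional subject ids (default `s1`, `s2`, ...).
#' @return a `cohort_table` object.
#' @export
cohort_table <- function(values, sex, age = NULL, wave = 1L,
                         schema = default_schema(), subject = NULL) {
  nodes <- node_names(schema)
  if (length(nodes) != 11L)
    stop("schema must declare exactly 11 network_node variables, got ",
         length(nodes))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) colnames(values) <- nodes
  if (!identical(colnames(values), nodes))
    stop("value columns must match schema network nodes in order")
  n <- nrow(values)
  if (is.null(subject)) subject <- paste0("s", seq_len(n))
  sex <- as.character(sex)
  if (length(sex) != n) stop("sex must have one entry per subject")
  if (anyNA(sex)) {
    stop("missing sex for subject(s): ",
         paste(subject[is.na(sex)], collapse = ", "))
  }
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (is.null(age)) age <- rep(NA_real_, n)
  validate_values(values, schema)
  for (s in c("male", "female")) {
    idx <- sex == s
    if (any(idx)) {
      allmiss <- colSums(!is.na(values[idx, , drop = FALSE])) == 0
      if (any(allmiss))
        stop("variable(s) entirely missing in ", s, " stratum: ",
             paste(nodes[allmiss], collapse = ", "))
    }
  }
  structure(list(subject = as.character(subject), sex = sex,
                 age = as.numeric(age), wave = as.integer(wave),
                 values = values, schema = schema),
            class = "cohort_table")
}

validate_values <- function(values, schema) {
  nodes <- node_names(schema)
  for (j in seq_along(nodes)) {
    v <- values[, j]
    row <- schema[schema$name == nodes[j], ]
    obs <- v[!is.na(v)]
    if (row$level == "binary" && !all(obs %in% c(0, 1)))
      stop("binary variable ", nodes[j], " has values outside {0,1} at row ",
           which(!is.na(v) & !(v %in% c(0, 1)))[1])
    if (row$level == "ordinal") {
      bad <- !is.na(v) & (v < row$lower | v > row$upper | v != round(v))
      if (any(bad))
        stop("ordinal variable ", nodes[j], " out of range [", row$lower,
             ", ", row$upper, "] at row ", which(bad)[1])
    }
  }
  invisible(TRUE)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table: ", nrow(x$values), " subjects x ",
      ncol(x$values), " network nodes (wave ", unique(x$wave), ")\n",
      sep = "")
  cat("  sex: ", sum(x$sex == "male"), " male / ",
      sum(x$sex == "female"), " female;  missing cells: ",
      sum(is.na(x$values)), "\n", sep = "")
  invisible(x)
}

#' Read a cohort CSV
#'
#' Expects one row per subject with columns `subject`, `sex`, `age`, `wave`
#' followed by the schema's network-node variables. Missing cells may be
#' encoded as the empty string or `NA`.
#'
#' @param path CSV file path.
#' @param schema a [variable_schema()].
#' @return a [cohort_table()].
#' @export
read_cohort_csv <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), check.names = FALSE)
  nodes <- node_names(schema)
  meta <- c("subject", "sex", "age", "wave")
  unknown <- setdiff(names(df), c(meta, nodes))
  if (length(unknown))
    stop("unknown column(s) in ", path, ": ", paste(unknown, collapse = ", "))
  missing_cols <- setdiff(c("sex", nodes), names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  values <- as.matrix(df[, nodes, drop = FALSE])
  storage.mode(values) <- "double"
  cohort_table(values, sex = df$sex,
               age = if ("age" %in% names(df)) df$age else NULL,
               wave = if ("wave" %in% names(df)) df$wave[1] else 1L,
               schema = schema,
               subject = if ("subject" %in% names(df)) df$subject else NULL)
}

#' Write a cohort table to CSV (missing cells as empty strings)
#'
#' @param table a [cohort_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  df <- data.frame(subject = table$subject, sex = table$sex,
                   age = table$age, wave = table$wave,
                   as.data.frame(table$values), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Split a cohort by sex
#'
#' @param table a [cohort_table()].
#' @return named list with elements `male` and `female`, both cohort tables.
#' @export
split_by_sex <- function(table) {
  out <- lapply(c(male = "male", female = "female"), function(s) {
    idx <- table$sex == s
    if (sum(idx) < 2)
      stop("insufficient data: fewer than 2 subjects in ", s, " stratum")
    cohort_table(table$values[idx, , drop = FALSE], table$sex[idx],
                 table$age[idx], table$wave, table$schema,
                 table$subject[idx])
  })
  out
}

#' Descriptive summary per variable and sex
#'
#' For continuous variables reports n observed/missing, mean and SD; for
#' ordinal and binary variables additionally tabulates level counts.
#'
#' @param table a [cohort_table()].
#' @return a data frame with one row per (variable, sex).
#' @export
summarize_cohort <- function(table) {
  nodes <- node_names(table$schema)
  rows <- list()
  for (s in c("male", "female")) {
    idx <- table$sex == s
    if (!any(idx)) next
    for (j in seq_along(nodes)) {
      v <- table$values[idx, j]
      obs <- v[!is.na(v)]
      lev <- table$schema$level[table$schema$name == nodes[j]]
      counts <- if (lev != "continuous") {
        paste(sprintf("%g:%d", sort(unique(obs)),
                      tabulate(match(obs, sort(unique(obs))))),
              collapse = " ")
      } else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        variable = nodes[j], sex = s, n_obs = length(obs),
        n_missing = sum(is.na(v)),
        mean = if (length(obs)) mean(obs) else NA_real_,
        sd = if (length(obs) > 1) stats::sd(obs) else
          if (length(obs) == 1) NA_real_ else NA_real_,
        levels = counts, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
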