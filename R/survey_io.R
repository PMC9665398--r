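# Domain vocabulary -----------------------------------------------------------

#' Collision-programming options
#'
#' The three collision-response programs a driverless car can carry:
#' `"MOST"` (minimise total casualties; the reference program), `"OCCUPANTS"`
#' (always protect the car's occupants) and `"PEDESTRIANS"` (always protect
#' pedestrians). Categorical preference questions additionally offer
#' `"RANDOM"` (the car decides at random); see [preference_choices()].
#'
#' @return Character vector of program labels, in canonical order.
#' @export
programs <- function() c("MOST", "OCCUPANTS", "PEDESTRIANS")

#' @rdname programs
#' @export
preference_choices <- function() c(programs(), "RANDOM")

#' Canonical price grid, framing labels and mandate conditions
#'
#' `canonical_prices()` returns the three price points of the discrete-choice
#' design in thousands of pounds. `frames()` lists the framings under which
#' the categorical purchase-preference question is asked, `conditions()` the
#' purchase-willingness (Likert) conditions, and `countries()` the survey
#' populations.
#'
#' @return Character or numeric vector of labels.
#' @export
canonical_prices <- function() c(15, 19, 23)

#' @rdname canonical_prices
#' @export
frames <- function() c("UNFRAMED", "FAMILY_PASSENGER", "FAMILY_PEDESTRIAN", "MORAL")

#' @rdname canonical_prices
#' @export
conditions <- function() c("BASELINE", "MANDATE_MOST", "MANDATE_PED", "MANDATE_OCC")

#' @rdname canonical_prices
#' @export
countries <- function() c("UK", "JP")

# Program mandated by each non-baseline Likert condition.
mandated_program <- function(condition) {
  map <- c(MANDATE_MOST = "MOST", MANDATE_PED = "PEDESTRIANS",
           MANDATE_OCC = "OCCUPANTS")
  unname(map[condition])
}

#' Construct a car offer
#'
#' A candidate vehicle in the discrete-choice experiment: a collision program
#' plus a price in thousands of pounds.
#'
#' @param program One of `programs()`.
#' @param price Price in GBP thousands; must be positive.
#' @return A one-row data frame with columns `program` and `price`.
#' @export
car_offer <- function(program, price) {
  program <- match.arg(program, programs())
  if (!is.numeric(price) || length(price) != 1L || !is.finite(price) || price <= 0)
    stop("`price` must be a single positive number (GBP thousands)", call. = FALSE)
  data.frame(program = program, price = price)
}

# Design ----------------------------------------------------------------------

#' Enumerate the discrete-choice design
#'
#' Builds the full canonical design: all unordered pairs of distinct car
#' offers drawn from the 3 programs x 3 prices grid, giving choose(9, 2) = 36
#' scenarios. Offers are ordered by (program, price) with programs in the
#' order `MOST < OCCUPANTS < PEDESTRIANS`; the lexicographically earlier
#' offer of each pair is presented as car A. The enumeration is
#' deterministic: repeated calls return the identical table.
#'
#' @return A data frame with columns `scenario_id` (1-based), `model_a`,
#'   `price_a`, `model_b`, `price_b` (prices in GBP thousands).
#' @export
generate_choice_design <- function() {
  offers <- expand.grid(price = canonical_prices(), program = programs(),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  offers <- offers[order(match(offers$program, programs()), offers$price), ]
  n <- nrow(offers)
  idx <- utils::combn(n, 2)
  data.frame(
    scenario_id = seq_len(ncol(idx)),
    model_a = offers$program[idx[1, ]],
    price_a = offers$price[idx[1, ]],
    model_b = offers$program[idx[2, ]],
    price_b = offers$price[idx[2, ]],
    stringsAsFactors = FALSE
  )
}

#' Convert survey prices to the internal GBP-thousands scale
#'
#' The UK survey quotes prices in pounds sterling, the Japanese survey in yen;
#' the two printed price lists are in the exact ratio 150 yen per pound, so
#' yen amounts are divided by 150 000 and pound amounts by 1 000. All model
#' utilities are expressed on the resulting GBP-thousands scale.
#'
#' @param amount Positive price(s) in whole currency units.
#' @param currency `"GBP"` or `"JPY"` (recycled across `amount`).
#' @return Price(s) in GBP thousands.
#' @export
convert_price <- function(amount, currency) {
  if (!is.numeric(amount) || any(!is.finite(amount)) || any(amount <= 0))
    stop("`amount` must be positive and finite", call. = FALSE)
  if (!all(currency %in% c("GBP", "JPY")))
    stop("`currency` must be \"GBP\" or \"JPY\"", call. = FALSE)
  divisor <- ifelse(currency == "GBP", 1000, 150000)
  amount / divisor
}

# Internal validation helpers --------------------------------------------------

stop_rows <- function(what, rows) {
  stop(sprintf("%s (row%s %s)", what, if (length(rows) > 1) "s" else "",
               paste(rows, collapse = ", ")), call. = FALSE)
}

check_columns <- function(df, needed, path) {
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column%s %s", path,
                 if (length(missing) > 1) "s" else "",
                 paste(missing, collapse = ", ")), call. = FALSE)
}

check_levels <- function(values, levels, what) {
  bad <- which(!(values %in% levels))
  if (length(bad)) stop_rows(sprintf("unknown %s label %s", what,
                                     paste(unique(values[bad]), collapse = ", ")), bad)
}

check_unique_key <- function(keys, what) {
  dup <- which(duplicated(keys))
  if (length(dup)) stop_rows(sprintf("duplicate %s", what), dup)
}

# Choice tables ----------------------------------------------------------------

#' Read and write discrete-choice tables
#'
#' `choices.csv` holds one row per (participant, scenario) decision together
#' with the two offers of the scenario, prices in whole pounds or whole yen
#' with a `currency` column. Prices are converted to GBP thousands on read
#' (see [convert_price()]); `write_choice_table()` writes UK rows in GBP and
#' JP rows in JPY, so `read_choice_table(write_choice_table(...))` is an
#' identity on the records.
#'
#' Malformed input (unknown enumeration labels, out-of-range prices,
#' inconsistent scenario definitions, duplicate participant/scenario keys)
#' raises an error naming the offending data rows.
#'
#' @param path File path of a UTF-8, comma-delimited table with a header row.
#' @param scenarios Scenario table as from [generate_choice_design()].
#' @param records Data frame with columns `participant_id`, `country`,
#'   `scenario_id`, `choice` (`"A"` or `"B"`).
#' @return `read_choice_table()` returns `list(scenarios =, records =)`.
#' @export
read_choice_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  check_columns(df, c("participant_id", "country", "scenario_id", "model_a",
                      "price_a", "model_b", "price_b", "currency", "choice"), path)
  check_levels(df$country, countries(), "country")
  check_levels(df$model_a, programs(), "program")
  check_levels(df$model_b, programs(), "program")
  check_levels(df$currency, c("GBP", "JPY"), "currency")
  check_levels(df$choice, c("A", "B"), "choice")
  sid <- suppressWarnings(as.integer(df$scenario_id))
  if (anyNA(sid)) stop_rows("non-integer scenario_id", which(is.na(sid)))
  pa <- suppressWarnings(as.numeric(df$price_a))
  pb <- suppressWarnings(as.numeric(df$price_b))
  bad <- which(is.na(pa) | is.na(pb) | pa <= 0 | pb <= 0)
  if (length(bad)) stop_rows("invalid price", bad)
  check_unique_key(paste(df$participant_id, sid), "(participant_id, scenario_id) key")

  records <- data.frame(participant_id = df$participant_id, country = df$country,
                        scenario_id = sid, choice = df$choice,
                        stringsAsFactors = FALSE)
  scen <- data.frame(scenario_id = sid,
                     model_a = df$model_a,
                     price_a = convert_price(pa, df$currency),
                     model_b = df$model_b,
                     price_b = convert_price(pb, df$currency),
                     stringsAsFactors = FALSE)
  key <- paste(scen$model_a, scen$price_a, scen$model_b, scen$price_b)
  first <- !duplicated(scen$scenario_id)
  # a scenario_id must always describe the same pair of offers
  ref <- tapply(key, scen$scenario_id, function(k) k[1])
  bad <- which(key != ref[as.character(scen$scenario_id)])
  if (length(bad)) stop_rows("scenario_id redefined with different offers", bad)
  same <- which(scen$model_a == scen$model_b & scen$price_a == scen$price_b)
  if (length(same)) stop_rows("car_a and car_b are identical", same)
  scenarios <- scen[first, , drop = FALSE]
  scenarios <- scenarios[order(scenarios$scenario_id), , drop = FALSE]
  rownames(scenarios) <- NULL
  list(scenarios = scenarios, records = records)
}

#' @rdname read_choice_table
#' @export
write_choice_table <- function(path, scenarios, records) {
  stopifnot(all(c("participant_id", "country", "scenario_id", "choice") %in%
                  names(records)))
  m <- match(records$scenario_id, scenarios$scenario_id)
  if (anyNA(m)) stop_rows("scenario_id not present in design", which(is.na(m)))
  currency <- ifelse(records$country == "JP", "JPY", "GBP")
  mult <- ifelse(currency == "JPY", 150000, 1000)
  out <- data.frame(
    participant_id = records$participant_id,
    country = records$country,
    scenario_id = records$scenario_id,
    model_a = scenarios$model_a[m],
    price_a = scenarios$price_a[m] * mult,
    model_b = scenarios$model_b[m],
    price_b = scenarios$price_b[m] * mult,
    currency = currency,
    choice = records$choice,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Preference tables -------------------------------------------------------------

#' Read and write categorical preference tables
#'
#' `preferences.csv` holds one row per (participant, frame) with the chosen
#' program (or `RANDOM`). One response per participant and frame is enforced.
#'
#' @param path File path (UTF-8 CSV with header).
#' @param responses Data frame with columns `participant_id`, `country`,
#'   `frame`, `choice`.
#' @return `read_preference_table()` returns the validated data frame.
#' @export
read_preference_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  check_columns(df, c("participant_id", "country", "frame", "choice"), path)
  check_levels(df$country, countries(), "country")
  check_levels(df$frame, frames(), "frame")
  check_levels(df$choice, preference_choices(), "preference choice")
  check_unique_key(paste(df$participant_id, df$frame), "(participant_id, frame) key")
  rownames(df) <- NULL
  df
}

#' @rdname read_preference_table
#' @export
write_preference_table <- function(path, responses) {
  check_columns(responses, c("participant_id", "country", "frame", "choice"), "responses")
  utils::write.csv(responses[, c("participant_id", "country", "frame", "choice")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Likert tables ------------------------------------------------------------------

#' Read and write purchase-willingness (Likert) tables
#'
#' `likert.csv` holds one row per (participant, condition) with the 1-7
#' willingness-to-purchase response (1 = not likely, 7 = extremely likely).
#' Responses outside 1..7 or duplicate (participant, condition) keys raise an
#' error naming the offending rows.
#'
#' @param path File path (UTF-8 CSV with header).
#' @param responses Data frame with columns `participant_id`, `country`,
#'   `condition`, `response`.
#' @return `read_likert_table()` returns the validated data frame with an
#'   integer `response` column.
#' @export
read_likert_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  check_columns(df, c("participant_id", "country", "condition", "response"), path)
  check_levels(df$country, countries(), "country")
  check_levels(df$condition, conditions(), "condition")
  resp <- suppressWarnings(as.integer(df$response))
  bad <- which(is.na(resp) | resp < 1L | resp > 7L | df$response != as.character(resp))
  if (length(bad)) stop_rows("Likert response outside 1..7", bad)
  check_unique_key(paste(df$participant_id, df$condition),
                   "(participant_id, condition) key")
  df$response <- resp
  rownames(df) <- NULL
  df
}

#' @rdname read_likert_table
#' @export
write_likert_table <- function(path, responses) {
  check_columns(responses, c("participant_id", "country", "condition", "response"),
                "responses")
  utils::write.csv(responses[, c("participant_id", "country", "condition", "response")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop participants with incomplete response sets
#'
#' Mirrors the study's inclusion rule that only participants providing full
#' data enter the analysis: participants missing any of the required keys
#' (scenarios, frames or conditions) are removed, with a warning giving the
#' number dropped.
#'
#' @param df Long response table with a `participant_id` column.
#' @param key_col Column holding the within-participant key.
#' @param required Vector of key values each participant must have.
#' @return The filtered table.
#' @export
drop_incomplete <- function(df, key_col, required) {
  have <- tapply(df[[key_col]], df$participant_id,
                 function(k) all(required %in% k))
  keep_ids <- names(have)[have]
  dropped <- sum(!have)
  if (dropped > 0)
    warning(sprintf("dropped %d participant(s) with incomplete responses", dropped),
            call. = FALSE)
  df[df$participant_id %in% keep_ids, , drop = FALSE]
}
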