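#!/usr/bin/env Rscript

# thin shell entry point over the package CLI:
#   Rscript scripts/cryptcoal <command> [--config=FILE] [--out=DIR] ...
suppressPackageStartupMessages(library(cryptcoal))
status <- crypt_cli(commandArgs(trailingOnly = TRUE))
quit(save = "no", status = status)
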