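Package: habitminer
Title: Activity Recognition and Habit Mining from Ambient Smart-Home Sensor Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for mining daily habits of a single resident
    from ambient binary-sensor event logs (CASAS dialect). Sensor events are
    tokenized ("M011ON"), frequency-index encoded and cut into fixed-size
    sliding sensor-event windows; a compact embedding + one-dimensional U-Net
    (with FCN and LSTM baselines, all implemented on base matrix operations)
    labels each window with an activity of daily living; classified behavior
    sequences are itemized into time-binned daily transactions; a from-scratch
    FP-Growth miner extracts frequent itemsets and association rules; and a
    timestamp-gap filter keeps only rules whose behaviors occur close together
    in time, yielding candidate habits scored by precision against planted
    ground truth. Includes a deterministic synthetic smart-home simulator that
    emits CASAS-format labeled event streams for testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
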