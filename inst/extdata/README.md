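# Bundled fixtures

`synthetic_invitro_monolayer.csv` — a SYNTHETIC stand-in reference table,
hand-entered to be qualitatively plausible for a monolayer ATR-inhibition
experiment (gammaH2AX-positive percentages and cell counts at 0/24/48/72 h
for several applied concentrations). It exists so that the fixture loader,
validation and RMSE comparison machinery can be exercised; it is NOT
experimental data, and RMSE values computed against it say nothing about
agreement with any published experiment. To compare against real
measurements, transcribe them into a CSV with the same columns
(`source,dose,metric,time,mean,dispersion`) and pass it to `load_fixture()`
or the `compare` CLI subcommand.
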