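format = radarhr-scene-1
snr_db = 20
duration = 40
seed = 42
target1.range = 0.8
target1.azimuth = 0
target1.reflectivity = 1
target1.respiration_frequency = 0.3
target1.respiration_amplitude = 0.004
target1.respiration_harmonics = 2:0.1,3:0.02
target1.heartbeat_frequency = 1.233
target1.heartbeat_amplitude = 0.00015
target1.respiration_phase = 0
target1.heartbeat_phase = 0
target2.range = 1.2
target2.azimuth = 25
target2.reflectivity = 1
target2.respiration_frequency = 0.25
target2.respiration_amplitude = 0.004
target2.respiration_harmonics = 2:0.1,3:0.02
target2.heartbeat_frequency = 1.45
target2.heartbeat_amplitude = 0.00015
target2.respiration_phase = 1.1
target2.heartbeat_phase = 0
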