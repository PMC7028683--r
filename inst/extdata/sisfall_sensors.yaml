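# Sensor schema for the SisFall raw-file dialect: three tri-axial sensors
# per line, comma-separated integer ADC readings, in this column order.
# Conversion to physical units: value * 2 * range / 2^resolution_bits.
sensors:
  - name: ADXL345        # wide-range accelerometer
    range: 16            # +/- g
    resolution_bits: 13
    unit: g
  - name: ITG3200        # gyroscope
    range: 2000          # +/- deg/s
    resolution_bits: 16
    unit: deg/s
  - name: MMA8451Q       # low-range accelerometer
    range: 8             # +/- g
    resolution_bits: 14
    unit: g
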