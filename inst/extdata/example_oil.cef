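<?xml version="1.0" encoding="UTF-8"?>
<CEF version="1.0">
  <CompoundList>
    <Compound>
      <Location mz="413.3429" rt="24.8100" height="185000.00"/>
      <CompoundScores>
        <CpdScore score="96.40"/>
      </CompoundScores>
    </Compound>
    <Compound>
      <Location mz="337.1082" rt="13.6600" height="52000.00"/>
      <CompoundScores>
        <CpdScore score="88.10"/>
      </CompoundScores>
      <Spectrum type="MS1" ignored="yes"/>
    </Compound>
    <Compound>
      <Location mz="203.1076" rt="12.7600" height="640000.00"/>
    </Compound>
  </CompoundList>
</CEF>
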