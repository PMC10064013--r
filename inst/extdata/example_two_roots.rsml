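<?xml version="1.0" encoding="UTF-8"?>
<rsml>
  <metadata>
    <version>1</version>
    <unit>cm</unit>
    <software>hand-built example</software>
  </metadata>
  <scene>
    <plant id="1" label="example">
      <root ID="1" label="bn0">
        <properties>
          <branching_number>0</branching_number>
          <insertion_position>0.000000</insertion_position>
          <insertion_angle>10.000000</insertion_angle>
        </properties>
        <geometry>
          <polyline>
            <point x="0.000000" y="0.000000" z="0.000000"/>
            <point x="0.000000" y="0.000000" z="1.000000"/>
            <point x="0.000000" y="0.000000" z="2.000000"/>
          </polyline>
        </geometry>
        <functions>
          <function name="diameter" domain="polyline">
            <sample value="0.060000"/>
            <sample value="0.060000"/>
            <sample value="0.060000"/>
          </function>
        </functions>
        <root ID="2" label="bn1">
          <properties>
            <branching_number>1</branching_number>
            <insertion_position>1.000000</insertion_position>
            <insertion_angle>48.200000</insertion_angle>
          </properties>
          <geometry>
            <polyline>
              <point x="0.000000" y="0.000000" z="1.000000"/>
              <point x="0.500000" y="0.000000" z="1.500000"/>
            </polyline>
          </geometry>
          <functions>
            <function name="diameter" domain="polyline">
              <sample value="0.030000"/>
              <sample value="0.030000"/>
            </function>
          </functions>
        </root>
      </root>
    </plant>
  </scene>
</rsml>
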